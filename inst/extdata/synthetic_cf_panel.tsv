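1111111111111111111	0.20000
2221111111111221222	0.12000
1111111122222111111	0.10000
2221111122222221222	0.08000
1112222111111221222	0.05000
2222222122222111111	0.03000
1112222122222111111	0.02708
1111121111111111111	0.01786
2221111111211221222	0.01786
1111111122222112111	0.01786
2121111122222221222	0.01786
1112221111111221222	0.01786
2222222122212111111	0.01786
1112222122222111211	0.01786
1121111111111111111	0.01786
2221111211111221222	0.01786
1111111122221111111	0.01786
2221111122222221212	0.01786
1111222111111221222	0.01786
2222222112222111111	0.01786
1112222122222211111	0.01786
1111111111111111112	0.01786
2221211111111221222	0.01786
1111111121222111111	0.01786
2221111122222211222	0.01786
2112222111111221222	0.01786
2222212122222111111	0.01786
1112222122122111111	0.01786
1111111111111112111	0.01786
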
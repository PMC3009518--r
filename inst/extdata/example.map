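snp1 1 0.00 1
snp2 1 0.01 10001
snp3 1 0.02 20001
snp4 1 0.03 30001
snp5 1 0.04 40001
snp6 1 0.05 50001
snp7 1 0.06 60001
snp8 1 0.07 70001
snp9 1 0.08 80001
snp11 1 0.10 100001
snp12 1 0.11 110001
snp13 1 0.12 120001
snp14 1 0.13 130001
snp15 1 0.14 140001
snp16 1 0.15 150001
snp17 1 0.16 160001
snp18 1 0.17 170001
snp19 1 0.18 180001
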
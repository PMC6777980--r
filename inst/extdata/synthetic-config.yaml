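# Synthetic 8-region paired experiment (generator seed 314); file paths
# are relative to this config file.
regions: synthetic-regions.csv
tracing: synthetic-tracing-counts.csv
tractography: synthetic-tractography-counts.csv
seed: 101
B: 500
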
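# Example configuration: cis drug-target MR of glucokinase (GCK) activation
# proxied by HbA1c-lowering variants. Paths are placeholders for the external
# exposure/outcome summary statistics; all thresholds are the working
# defaults of the drug-target design.
mode: cis
region:
  chrom: "7"
  start: 44182812          # GCK coding region, GRCh37
  end: 44229038
  flank: 100000            # +/- 100 kb
p_threshold: 5.0e-8
clump_window_bases: 10000000   # 10 Mb
r2_threshold: 0.3              # genome-wide design would use 0.001
palindromic_eaf_limit: 0.42
n_sim: 1000
seed: 1
alpha: 0.05
exposure:
  path: data/hba1c_exposure.tsv
  dialect: magic
  trait_name: HbA1c
  trait_unit: "%"
outcomes:
  - name: memory_loss
    path: data/memory_loss.tsv
    dialect: finngen-r5
    binary: true
  - name: intelligence
    path: data/intelligence.tsv
    dialect: generic
    binary: false
ld:
  path: data/ld_r2.tsv
  kind: r2
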
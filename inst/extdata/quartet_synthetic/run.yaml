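# Example configuration for run_pipeline() / aaf.R run, using the bundled
# synthetic 4-taxon FASTA fixture (paths relative to this directory).
taxa:
  a:
    files: a.fasta
  b:
    files: b.fasta
  c:
    files: c.fasta
  d:
    files: d.fasta
k: 11
filter: false
seed: 1
output_dir: aaf_quartet_run
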
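# Demo holobiont community: a dominant host with cyanobiont background, one
# genuinely resident endophyte, and two artifact candidates (a shared
# rRNA-like locus and a chimeric scaffold). Small enough to run end-to-end
# in well under a minute on one CPU.
seed: 42
community:
  n_reads: 20000
  read_length: 147
  error_rate: 0.005
  replicate_id: demo
  genomes:
    - name: host
      length: 400000
      gc: 0.40
    - name: cyanobiont
      length: 200000
      gc: 0.42
      shared_locus: {length: 5000, identity: 0.99}
    - name: endo_present
      length: 500000
      gc: 0.55
      divergence: 0.02
    - name: endo_locus_only
      length: 500000
      gc: 0.55
      shared_locus: {length: 5000, identity: 0.99, position: 100000}
    - name: endo_chimeric
      length: 500000
      gc: 0.55
      chimera_with: {host: host, junction: 0.9, host_start: 0}
  abundances:
    host: 0.78
    cyanobiont: 0.19
    endo_present: 0.03
    endo_locus_only: 0.0
    endo_chimeric: 0.0
references: [endo_present, endo_locus_only, endo_chimeric]
recruitment:
  pos_bin: 50000
  id_bin: 1
  id_floor: 70
  min_identity: 97
presence:
  hi_identity: 90
  min_reads: 50
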
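# Small demonstration pipeline configuration: 500 loci under the
# reciprocal-monophyly model, all seven samples, full stage set.
model: fig5a
seed: 42
n_loci: 500
locus_length: 1000
mu: 1.0e-8
outgroup: GLJ
dogs: [BOX, BSJ, DNG]
wolves: [ISW, CRW, CHW]
window_loci: 10
block_loci: 25
bootstrap_reps: 50
het_window_bp: 100000
outdir: canidemog_demo
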
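{
  "_comment": "Synthetic example layout. Module 2's B sub-pattern '++--' is the one documented for the pictorial phenotype mapping; the B sub-patterns of modules 1, 3 and 4 are not documented anywhere and are synthetic choices fixed here for reproducible examples.",
  "n_modules": 4,
  "module_width": 4,
  "b_subpatterns": ["+-+-", "++--", "+--+", "+++-"],
  "train_indices": [1, 2, 3],
  "K": 20000,
  "total_generations": null,
  "order_policy": "cyclic",
  "seed": 1
}
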
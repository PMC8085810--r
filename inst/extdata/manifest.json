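{
 "buryn_brandl_reconstructed.csv": {
  "md5": "18579741106796797e6a51181b6e929f",
  "n_rows": 52
 },
 "table10_cephalisation.csv": {
  "md5": "cd9cf7d83ce82c50480d3afec7ce5dbc",
  "n_rows": 24
 },
 "table11_12_parasitines.csv": {
  "md5": "b18877b8e870f261ebde5313e74aabed",
  "n_rows": 95
 },
 "table13_dataset_means.csv": {
  "md5": "92146f673abb8e1032f6ec85f81636a0",
  "n_rows": 8
 },
 "table13_relative_measures.csv": {
  "md5": "5a431c031259aa99cefd30bd852b32a6",
  "n_rows": 60
 },
 "table14_15_heuristics.csv": {
  "md5": "621be98eb16c5461bbc40a45c5ba1f98",
  "n_rows": 60
 },
 "table16_habitats.csv": {
  "md5": "fd24e6664ca03654041b5b1172174013",
  "n_rows": 15
 },
 "table17_holothyrids.csv": {
  "md5": "60558466fe083a17bdfe645edbe285b0",
  "n_rows": 14
 },
 "table18_opilioacarids.csv": {
  "md5": "b50352ff540c011c2d35b19a0504958c",
  "n_rows": 32
 },
 "table2_new_species_means.csv": {
  "md5": "5a4774526e68441057d3a5fa5bd216cf",
  "n_rows": 8
 },
 "table3_species_means.csv": {
  "md5": "b584fb7f0c57cc9ffc024b68130404cf",
  "n_rows": 60
 },
 "table5_pca_loadings.csv": {
  "md5": "d1c66bc99cdd90b0d03a50a10d3902bb",
  "n_rows": 4
 },
 "table6_phytoseiid_validation.csv": {
  "md5": "0736fa92e9700bf05889708e797db22e",
  "n_rows": 18
 },
 "table8_test_predictions.csv": {
  "md5": "e6de3de7cbf2f344c04e615805819df5",
  "n_rows": 33
 },
 "training_labels.csv": {
  "md5": "e5c6d81c49d7997c0fba17e831917f17",
  "n_rows": 60
 }
}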
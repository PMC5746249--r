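# Default grouping of PSI-MI interaction-detection-method ids into the 8
# groups used for evidence deduplication. Edit freely: pass the path of a
# modified copy to detection_groups(). Unlisted ids fall into "other".
tap:
  - MI:0676   # tandem affinity purification
coip:
  - MI:0019   # coimmunoprecipitation
  - MI:0006   # anti bait coimmunoprecipitation
  - MI:0007   # anti tag coimmunoprecipitation
pulldown:
  - MI:0096   # pull down
two_hybrid:
  - MI:0018   # two hybrid
  - MI:0397   # two hybrid array
  - MI:0398   # two hybrid pooling approach
  - MI:1112   # two hybrid prey pooling approach
pca:
  - MI:0090   # protein complementation assay
  - MI:0112   # ubiquitin reconstruction
biophysical:
  - MI:0013   # biophysical
  - MI:0065   # isothermal titration calorimetry
  - MI:0107   # surface plasmon resonance
  - MI:0114   # x-ray crystallography
  - MI:0077   # nuclear magnetic resonance
other_affinity:
  - MI:0004   # affinity chromatography technology
other: []
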
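financial:
  discount_rate: 0.08
  lifetime: 25
  base_year: 2024.0
  annualisation_method: capital_recovery_factor
basis:
  silage_capacity: 33333.0
  protein_extraction_efficiency: 15.0
  lipid_yield: 10.0
  lignin_yield: 12.0
  ad_solids: 28500.0
yields:
  solubilized_fraction: 0.22
  protein_liquid_recovery: 0.52
  concentrate_purity: 0.6
  crude_protein_content: 0.15
prices:
  protein_price:
    kind: normal
    mean: 15.0
    sd: 2.55106728462327
  lipid_biomass_price:
    kind: truncated_normal
    mean: 3.0
    sd: 0.75
    lower: 2.0
    upper: 5.0
  residual_solids_price:
    kind: uniform
    mean: 0.08
    lower: 0.06
    upper: 0.1
  lignin_price:
    kind: truncated_normal
    mean: 0.1
    sd: 0.02
    lower: 0.05
    upper: 0.15
  silage_price:
    kind: uniform
    mean: 0.14
    lower: 0.1
    upper: 0.18
factors:
  direct:
    piping: 0.45
    electrical: 0.2
    foundations: 0.15
    utilities: 0.25
    installation: 0.45
  indirect: 0.25
equipment:
- name: twin_screw_extruder
  purchase_cost:
    kind: truncated_normal
    mean: 439744.040926746034529
    sd: 43974.404092674609274
    lower: 329808.030695059511345
    upper: 549680.051158432615921
  scenarios:
  - scenario1
  - scenario2
- name: feed_handling_mill
  purchase_cost:
    kind: truncated_normal
    mean: 180224.809747782011982
    sd: 18022.480974778201926
    lower: 135168.607310836494435
    upper: 225281.012184727529529
  scenarios:
  - scenario1
  - scenario2
- name: hydrocyclone
  purchase_cost:
    kind: truncated_normal
    mean: 116531.51465053523134
    sd: 11653.151465053524589
    lower: 87398.635987901419867
    upper: 145664.393313169042813
  scenarios:
  - scenario1
  - scenario2
- name: membrane_unit
  purchase_cost:
    kind: truncated_normal
    mean: 334259.716090747038834
    sd: 33425.971609074702428
    lower: 250694.787068060279125
    upper: 417824.645113433827646
  scenarios:
  - scenario1
  - scenario2
- name: spray_dryer
  purchase_cost:
    kind: truncated_normal
    mean: 281579.183792366995476
    sd: 28157.918379236700275
    lower: 211184.387844275246607
    upper: 351973.979740458773449
  scenarios:
  - scenario1
  - scenario2
- name: tanks_and_pumps
  purchase_cost:
    kind: truncated_normal
    mean: 106869.148865922194091
    sd: 10686.914886592219773
    lower: 80151.861649441649206
    upper: 133586.436082402738975
  scenarios:
  - scenario1
  - scenario2
- name: cip_system
  purchase_cost:
    kind: truncated_normal
    mean: 76791.585925900479197
    sd: 7679.158592590048102
    lower: 57593.689444425355759
    upper: 95989.482407375602634
  scenarios:
  - scenario1
  - scenario2
- name: hydrolysis_reactors
  purchase_cost:
    kind: truncated_normal
    mean: 704125.763842731365003
    sd: 70412.576384273139411
    lower: 528094.322882048552856
    upper: 880157.20480341417715
  scenarios:
  - scenario2
- name: fermenters
  purchase_cost:
    kind: truncated_normal
    mean: 1101100.931580316508189
    sd: 110110.093158031653729
    lower: 825825.698685237439349
    upper: 1376376.164475395577028
  scenarios:
  - scenario2
- name: lipid_recovery_centrifuge
  purchase_cost:
    kind: truncated_normal
    mean: 487442.996154479682446
    sd: 48744.2996154479697
    lower: 365582.247115859761834
    upper: 609303.745193099603057
  scenarios:
  - scenario2
- name: utilities_expansion
  purchase_cost:
    kind: truncated_normal
    mean: 288262.044749609252904
    sd: 28826.204474960926746
    lower: 216196.53356220695423
    upper: 360327.555937011551578
  scenarios:
  - scenario2
- name: yeast_seed_train
  purchase_cost:
    kind: truncated_normal
    mean: 203068.263672863307875
    sd: 20306.826367286332243
    lower: 152301.197754647466354
    upper: 253835.329591079149395
  scenarios:
  - scenario2
operating:
- name: silage_feedstock
  category: raw_material
  unit_price:
    kind: uniform
    mean: 140.0
    lower: 100.0
    upper: 180.0
  annual_usage: 33333.0
  scenarios:
  - scenario1
  - scenario2
- name: sodium_carbonate
  category: raw_material
  unit_price:
    kind: truncated_normal
    mean: 299.078595729317897
    sd: 29.907859572931791
    lower: 224.308946796988437
    upper: 373.848244661647357
  annual_usage: 1000.0
  scenarios:
  - scenario1
  - scenario2
- name: electricity
  category: utility
  unit_price:
    kind: truncated_normal
    mean: 114.04714205866884
    sd: 11.404714205866885
    lower: 85.53535654400163
    upper: 142.558927573336064
  annual_usage: 25000.0
  scenarios:
  - scenario1
  - scenario2
- name: steam
  category: utility
  unit_price:
    kind: truncated_normal
    mean: 31.516349810712246
    sd: 3.151634981071225
    lower: 23.637262358034185
    upper: 39.395437263390306
  annual_usage: 20000.0
  scenarios:
  - scenario1
  - scenario2
- name: process_water
  category: utility
  unit_price:
    kind: truncated_normal
    mean: 2.028629244324352
    sd: 0.202862924432435
    lower: 1.521471933243264
    upper: 2.53578655540544
  annual_usage: 200000.0
  scenarios:
  - scenario1
  - scenario2
- name: labour
  category: labour
  unit_price:
    kind: truncated_normal
    mean: 1827341.357859087409452
    sd: 182734.135785908758407
    lower: 1370506.018394315615296
    upper: 2284176.697323859203607
  annual_usage: 1.0
  scenarios:
  - scenario1
  - scenario2
- name: maintenance
  category: maintenance
  unit_price:
    kind: truncated_normal
    mean: 522426.512660862063058
    sd: 52242.651266086206306
    lower: 391819.884495646576397
    upper: 653033.140826077549718
  annual_usage: 1.0
  scenarios:
  - scenario1
  - scenario2
- name: membrane_replacement
  category: membrane_replacement
  unit_price:
    kind: truncated_normal
    mean: 832813.316411618492566
    sd: 83281.331641161857988
    lower: 624609.987308713840321
    upper: 1041016.645514523144811
  annual_usage: 1.0
  scenarios:
  - scenario1
  - scenario2
- name: fixed_overheads
  category: fixed
  unit_price:
    kind: truncated_normal
    mean: 1964488.820793278981
    sd: 196448.882079327915562
    lower: 1473366.615594959119335
    upper: 2455611.025991598609835
  annual_usage: 1.0
  scenarios:
  - scenario1
  - scenario2
- name: hydrolysis_enzymes
  category: raw_material
  unit_price:
    kind: truncated_normal
    mean: 5023.996285354731299
    sd: 502.399628535473141
    lower: 3767.997214016048474
    upper: 6279.995356693414578
  annual_usage: 240.0
  scenarios:
  - scenario2
- name: fermentation_nutrients
  category: raw_material
  unit_price:
    kind: truncated_normal
    mean: 1000.682778212176913
    sd: 100.068277821217691
    lower: 750.512083659132713
    upper: 1250.853472765221113
  annual_usage: 500.0
  scenarios:
  - scenario2
- name: fermentation_electricity
  category: utility
  unit_price:
    kind: truncated_normal
    mean: 117.559800963509701
    sd: 11.755980096350971
    lower: 88.169850722632276
    upper: 146.949751204387127
  annual_usage: 2500.0
  scenarios:
  - scenario2
scenarios:
  scenario1:
    revenue_streams:
      protein_product: protein_price
      lignin: lignin_price
      ad_solids: residual_solids_price
    includes_fermentation: no
  scenario2:
    revenue_streams:
      protein_product: protein_price
      lignin: lignin_price
      ad_solids: residual_solids_price
      lipid_rich_yeast: lipid_biomass_price
    includes_fermentation: yes

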
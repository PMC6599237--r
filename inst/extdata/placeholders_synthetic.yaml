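utilities:
  rrms:
  - 0.88
  - 0.8175
  - 0.755
  - 0.6925
  - 0.63
  - 0.5675
  - 0.505
  - 0.4425
  - 0.38
  spms_disutility: 0.0092
  relapse_disutility: 0.0437
  provenance: 'placeholder (synthetic, seed 20190628): stands in for the EDSS-stratified
    RRMS utilities from pivotal trials, which the published analysis references but
    does not print'
spms:
  conversion:
  - 0.02
  - 0.03
  - 0.04
  - 0.05
  - 0.06
  - 0.07
  - 0.08
  - 0.09
  - 0.1
  progression:
  - 0.0
  - 0.75
  - 0.2
  - 0.05
  - 0.0
  provenance: 'placeholder (synthetic, seed 20190628): stands in for the registry-based
    SPMS conversion and progression probabilities, which the published analysis references
    but does not print'
mortality:
  age:
  - 0
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  - 12
  - 13
  - 14
  - 15
  - 16
  - 17
  - 18
  - 19
  - 20
  - 21
  - 22
  - 23
  - 24
  - 25
  - 26
  - 27
  - 28
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  - 101
  - 102
  - 103
  - 104
  - 105
  - 106
  - 107
  - 108
  - 109
  - 110
  female:
  - 0.00011499
  - 0.00011647
  - 0.0001181
  - 0.00011988
  - 0.00012184
  - 0.00012399
  - 0.00012636
  - 0.00012896
  - 0.00013181
  - 0.00013495
  - 0.00013839
  - 0.00014217
  - 0.00014633
  - 0.0001509
  - 0.00015592
  - 0.00016143
  - 0.00016748
  - 0.00017413
  - 0.00018144
  - 0.00018947
  - 0.00019828
  - 0.00020797
  - 0.00021861
  - 0.0002303
  - 0.00024314
  - 0.00025725
  - 0.00027275
  - 0.00028977
  - 0.00030848
  - 0.00032902
  - 0.00035159
  - 0.00037638
  - 0.00040362
  - 0.00043354
  - 0.00046641
  - 0.00050252
  - 0.00054218
  - 0.00058575
  - 0.00063361
  - 0.00068619
  - 0.00074395
  - 0.0008074
  - 0.00087709
  - 0.00095365
  - 0.00103774
  - 0.00113012
  - 0.00123159
  - 0.00134305
  - 0.00146548
  - 0.00159996
  - 0.00174768
  - 0.00190993
  - 0.00208814
  - 0.00228387
  - 0.00249886
  - 0.00273498
  - 0.0029943
  - 0.00327911
  - 0.0035919
  - 0.0039354
  - 0.00431261
  - 0.00472685
  - 0.00518171
  - 0.00568116
  - 0.00622955
  - 0.00683164
  - 0.00749265
  - 0.0082183
  - 0.00901486
  - 0.0098892
  - 0.01084881
  - 0.01190194
  - 0.01305757
  - 0.01432553
  - 0.0157166
  - 0.0172425
  - 0.01891607
  - 0.02075129
  - 0.02276345
  - 0.02496915
  - 0.02738651
  - 0.03003521
  - 0.03293666
  - 0.03611407
  - 0.03959261
  - 0.04339953
  - 0.04756426
  - 0.05211857
  - 0.05709666
  - 0.06253525
  - 0.06847371
  - 0.07495412
  - 0.08202128
  - 0.08972275
  - 0.09810883
  - 0.1072324
  - 0.11714884
  - 0.12791572
  - 0.13959249
  - 0.15223997
  - 0.16591979
  - 0.18069358
  - 0.196622
  - 0.2137636
  - 0.23217337
  - 0.2519011
  - 0.27298942
  - 0.2954716
  - 0.31936904
  - 0.34468849
  - 0.37141904
  male:
  - 0.00022997
  - 0.0002328
  - 0.00023589
  - 0.00023927
  - 0.00024297
  - 0.00024702
  - 0.00025145
  - 0.0002563
  - 0.0002616
  - 0.0002674
  - 0.00027375
  - 0.0002807
  - 0.0002883
  - 0.00029662
  - 0.00030572
  - 0.00031567
  - 0.00032657
  - 0.00033849
  - 0.00035153
  - 0.0003658
  - 0.00038142
  - 0.0003985
  - 0.0004172
  - 0.00043765
  - 0.00046003
  - 0.00048451
  - 0.00051131
  - 0.00054062
  - 0.00057269
  - 0.00060779
  - 0.00064618
  - 0.00068819
  - 0.00073416
  - 0.00078445
  - 0.00083947
  - 0.00089968
  - 0.00096555
  - 0.00103761
  - 0.00111646
  - 0.00120272
  - 0.00129711
  - 0.00140036
  - 0.00151334
  - 0.00163693
  - 0.00177215
  - 0.00192008
  - 0.00208191
  - 0.00225896
  - 0.00245265
  - 0.00266453
  - 0.00289631
  - 0.00314986
  - 0.00342722
  - 0.0037306
  - 0.00406245
  - 0.00442543
  - 0.00482243
  - 0.00525665
  - 0.00573154
  - 0.00625089
  - 0.00681884
  - 0.0074399
  - 0.00811901
  - 0.00886154
  - 0.00967336
  - 0.01056087
  - 0.01153105
  - 0.01259151
  - 0.01375053
  - 0.01501714
  - 0.01640117
  - 0.01791331
  - 0.0195652
  - 0.02136946
  - 0.02333984
  - 0.02549123
  - 0.0278398
  - 0.03040306
  - 0.03319997
  - 0.03625103
  - 0.0395784
  - 0.04320596
  - 0.04715944
  - 0.05146653
  - 0.05615693
  - 0.06126248
  - 0.0668172
  - 0.07285739
  - 0.07942162
  - 0.0865508
  - 0.09428812
  - 0.10267904
  - 0.11177113
  - 0.12161394
  - 0.13225878
  - 0.14375834
  - 0.15616634
  - 0.16953695
  - 0.18392412
  - 0.19938079
  - 0.21595787
  - 0.2337031
  - 0.25265966
  - 0.27286459
  - 0.29434699
  - 0.31712603
  - 0.34120866
  - 0.36658729
  - 0.3932372
  - 0.42111394
  - 0.45015074
  multiplier_rrms:
  - 1.1
  - 1.35
  - 1.6
  - 1.85
  - 2.1
  - 2.35
  - 2.6
  - 2.85
  - 3.1
  multiplier_spms:
  - 1.5
  - 1.8
  - 2.1
  - 2.4
  - 2.7
  - 3.0
  - 3.3
  - 3.6
  - 3.9
  provenance: 'placeholder (synthetic, seed 20190628): stands in for the national
    life tables and MS mortality multipliers, which the published analysis references
    but does not print'
adverse_events:
  natalizumab:
  - event: infusion_reaction
    serious: no
    annual_incidence: 0.1
    unit_cost: 150.0
    disutility: 0.05
    duration_fraction: 0.02
  - event: serious_hypersensitivity
    serious: yes
    annual_incidence: 0.005
    unit_cost: 8000.0
    disutility: 0.2
    duration_fraction: 0.25
  ifn_beta1a_44:
  - event: flu_like_symptoms
    serious: no
    annual_incidence: 0.5
    unit_cost: 60.0
    disutility: 0.03
    duration_fraction: 0.05
  - event: injection_site_reaction
    serious: no
    annual_incidence: 0.3
    unit_cost: 40.0
    disutility: 0.02
    duration_fraction: 0.03
  - event: serious_hepatotoxicity
    serious: yes
    annual_incidence: 0.01
    unit_cost: 3000.0
    disutility: 0.15
    duration_fraction: 0.2
  ifn_beta1b:
  - event: flu_like_symptoms
    serious: no
    annual_incidence: 0.5
    unit_cost: 60.0
    disutility: 0.03
    duration_fraction: 0.05
  - event: injection_site_reaction
    serious: no
    annual_incidence: 0.3
    unit_cost: 40.0
    disutility: 0.02
    duration_fraction: 0.03
  - event: serious_hepatotoxicity
    serious: yes
    annual_incidence: 0.01
    unit_cost: 3000.0
    disutility: 0.15
    duration_fraction: 0.2
  ifn_beta1a_30:
  - event: flu_like_symptoms
    serious: no
    annual_incidence: 0.5
    unit_cost: 60.0
    disutility: 0.03
    duration_fraction: 0.05
  - event: injection_site_reaction
    serious: no
    annual_incidence: 0.3
    unit_cost: 40.0
    disutility: 0.02
    duration_fraction: 0.03
  - event: serious_hepatotoxicity
    serious: yes
    annual_incidence: 0.01
    unit_cost: 3000.0
    disutility: 0.15
    duration_fraction: 0.2
  glatiramer:
  - event: injection_site_reaction
    serious: no
    annual_incidence: 0.3
    unit_cost: 40.0
    disutility: 0.02
    duration_fraction: 0.03
  - event: post_injection_reaction
    serious: no
    annual_incidence: 0.1
    unit_cost: 60.0
    disutility: 0.03
    duration_fraction: 0.02
  provenance: 'placeholder (synthetic, seed 20190628): stands in for the treatment-specific
    adverse-event incidences, costs and disutilities, which the published analysis
    references but does not print'
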
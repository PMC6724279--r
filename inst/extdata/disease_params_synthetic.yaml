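reference_hba1c: 9.2
complications:
- name: background_retinopathy
  baseline_hazard: 0.05
  rr_per_pct: 1.13
  fatality_prob: 0.0
  transient: no
- name: proliferative_retinopathy
  baseline_hazard: 0.035
  rr_per_pct: 1.13
  predecessor: background_retinopathy
  fatality_prob: 0.0
  transient: no
- name: macular_edema
  baseline_hazard: 0.02
  rr_per_pct: 1.13
  predecessor: background_retinopathy
  fatality_prob: 0.0
  transient: no
- name: severe_visual_loss
  baseline_hazard: 0.03
  rr_per_pct: 1.1
  predecessor: proliferative_retinopathy
  fatality_prob: 0.0
  transient: no
- name: cataract
  baseline_hazard: 0.012
  rr_per_pct: 1.05
  fatality_prob: 0.0
  transient: no
- name: microalbuminuria
  baseline_hazard: 0.045
  rr_per_pct: 1.12
  fatality_prob: 0.0
  transient: no
- name: gross_proteinuria
  baseline_hazard: 0.04
  rr_per_pct: 1.12
  predecessor: microalbuminuria
  fatality_prob: 0.0
  transient: no
- name: end_stage_renal_disease
  baseline_hazard: 0.035
  rr_per_pct: 1.1
  predecessor: gross_proteinuria
  fatality_prob: 0.0
  transient: no
- name: neuropathy
  baseline_hazard: 0.045
  rr_per_pct: 1.11
  fatality_prob: 0.0
  transient: no
- name: uninfected_ulcer
  baseline_hazard: 0.03
  rr_per_pct: 1.1
  predecessor: neuropathy
  fatality_prob: 0.0
  transient: yes
- name: infected_ulcer
  baseline_hazard: 0.25
  rr_per_pct: 1.05
  predecessor: uninfected_ulcer
  fatality_prob: 0.0
  transient: yes
- name: gangrene
  baseline_hazard: 0.08
  rr_per_pct: 1.05
  predecessor: infected_ulcer
  fatality_prob: 0.15
  transient: yes
- name: amputation
  baseline_hazard: 0.12
  rr_per_pct: 1.05
  predecessor: uninfected_ulcer
  fatality_prob: 0.08
  transient: no
- name: angina
  baseline_hazard: 0.008
  rr_per_pct: 1.08
  fatality_prob: 0.0
  transient: no
- name: myocardial_infarction
  baseline_hazard: 0.009
  rr_per_pct: 1.08
  fatality_prob: 0.2
  transient: no
- name: congestive_heart_failure
  baseline_hazard: 0.007
  rr_per_pct: 1.08
  fatality_prob: 0.1
  transient: no
- name: stroke
  baseline_hazard: 0.008
  rr_per_pct: 1.08
  fatality_prob: 0.25
  transient: no
- name: peripheral_vascular_disease
  baseline_hazard: 0.008
  rr_per_pct: 1.08
  fatality_prob: 0.0
  transient: no
mortality:
  age:
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
  male:
  - 0.0020865
  - 0.0022377
  - 0.0024
  - 0.002574
  - 0.0027607
  - 0.0029608
  - 0.0031755
  - 0.0034058
  - 0.0036527
  - 0.0039176
  - 0.0042016
  - 0.0045063
  - 0.004833
  - 0.0051834
  - 0.0055593
  - 0.0059624
  - 0.0063947
  - 0.0068584
  - 0.0073557
  - 0.007889
  - 0.008461
  - 0.0090745
  - 0.0097325
  - 0.0104382
  - 0.011195
  - 0.0120067
  - 0.0128773
  - 0.013811
  - 0.0148125
  - 0.0158865
  - 0.0170384
  - 0.0182738
  - 0.0195988
  - 0.0210199
  - 0.022544
  - 0.0241786
  - 0.0259318
  - 0.027812
  - 0.0298286
  - 0.0319915
  - 0.0343111
  - 0.0367989
  - 0.0394672
  - 0.0423288
  - 0.045398
  - 0.0486898
  - 0.0522202
  - 0.0560066
  - 0.0600675
  - 0.0644229
  - 0.0690941
  - 0.0741039
  - 0.0794771
  - 0.0852398
  - 0.0914204
  - 0.0980491
  - 0.1051585
  - 0.1127834
  - 0.1209611
  - 0.1297317
  - 0.1391383
  - 0.149227
  - 0.1600472
  - 0.1716519
  - 0.1840981
  - 0.1974467
  - 0.2117632
  - 0.2271178
  - 0.2435857
  - 0.2612476
  - 0.2801902
  - 0.3005063
  - 0.3222955
  - 0.3456645
  - 0.370728
  - 0.3976089
  - 0.4264387
  - 0.457359
  - 0.4905213
  - 0.5260881
  - 0.5642338
  - 0.6051454
  - 0.6490234
  - 0.6960829
  - 0.7465546
  - 0.8006859
  - 0.8587422
  - 0.921008
  - 0.9877886
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  female:
  - 0.0014779
  - 0.0015851
  - 0.0017
  - 0.0018233
  - 0.0019555
  - 0.0020973
  - 0.0022493
  - 0.0024124
  - 0.0025873
  - 0.0027749
  - 0.0029761
  - 0.0031919
  - 0.0034234
  - 0.0036716
  - 0.0039378
  - 0.0042233
  - 0.0045296
  - 0.004858
  - 0.0052103
  - 0.005588
  - 0.0059932
  - 0.0064278
  - 0.0068938
  - 0.0073937
  - 0.0079298
  - 0.0085048
  - 0.0091214
  - 0.0097828
  - 0.0104922
  - 0.0112529
  - 0.0120689
  - 0.0129439
  - 0.0138825
  - 0.0148891
  - 0.0159687
  - 0.0171265
  - 0.0183683
  - 0.0197002
  - 0.0211286
  - 0.0226606
  - 0.0243037
  - 0.0260659
  - 0.0279559
  - 0.0299829
  - 0.0321569
  - 0.0344886
  - 0.0369893
  - 0.0396713
  - 0.0425478
  - 0.0456329
  - 0.0489416
  - 0.0524903
  - 0.0562963
  - 0.0603782
  - 0.0647561
  - 0.0694515
  - 0.0744873
  - 0.0798882
  - 0.0856808
  - 0.0918933
  - 0.0985563
  - 0.1057025
  - 0.1133668
  - 0.1215868
  - 0.1304028
  - 0.1398581
  - 0.1499989
  - 0.1608751
  - 0.1725399
  - 0.1850504
  - 0.1984681
  - 0.2128586
  - 0.2282926
  - 0.2448457
  - 0.262599
  - 0.2816396
  - 0.3020608
  - 0.3239627
  - 0.3474526
  - 0.3726458
  - 0.3996656
  - 0.4286446
  - 0.4597249
  - 0.4930587
  - 0.5288095
  - 0.5671525
  - 0.6082757
  - 0.6523807
  - 0.6996836
  - 0.7504164
  - 0.8048277
  - 0.85
  - 1.0
acute_rates:
  minor_hypo: 30.0
  ketoacidosis: 4.0
  lactic_acidosis: 0.2
  edema: 2.0
esrd_modality_shares:
  hemodialysis: 0.5
  peritoneal_dialysis: 0.5
  transplant: 0.0
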
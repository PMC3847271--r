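base_year: 2013
neonatal_mortality: 30.0
child_1_59m_mortality: 40.0
stillbirth_rate: 20.0
maternal_mortality_ratio: 500.0
sub_band_weights:
  M1_5: 0.45
  M6_11: 0.25
  M12_23: 0.18
  M24_59: 0.12
cause_structures:
  STILLBIRTH:
    antepartum: 0.6
    intrapartum: 0.4
  MATERNAL:
    hemorrhage: 0.6
    maternal_sepsis: 0.4
  NEONATAL_0_1M:
    sepsis: 0.5
    asphyxia: 0.5
  M1_5:
    diarrhea: 0.555555555555556
    pneumonia: 0.444444444444444
  M6_11:
    diarrhea: 0.4
    pneumonia: 0.4
    malaria: 0.2
  M12_23:
    diarrhea: 0.35
    pneumonia: 0.35
    malaria: 0.3
  M24_59:
    diarrhea: 0.3
    pneumonia: 0.3
    malaria: 0.4
base_coverages:
  diarrhea_vaccine_1: 0.0
  diarrhea_vaccine_2: 0.0
  pneumonia_intv_a: 0.3
  pneumonia_intv_b: 0.4
live_births:
  '2013': 1000000.0
  '2014': 1000000.0
  '2015': 1000000.0
  '2016': 1000000.0
  '2017': 1000000.0
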
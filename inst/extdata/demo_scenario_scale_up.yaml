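name: scale_up
trajectories:
  diarrhea_vaccine_1:
    '2013': 0.5
    '2014': 0.5
    '2015': 0.5
    '2016': 0.5
    '2017': 0.5
  diarrhea_vaccine_2:
    '2013': 0.5
    '2014': 0.5
    '2015': 0.5
    '2016': 0.5
    '2017': 0.5
  pneumonia_intv_a:
    '2013': 0.5
    '2014': 0.5
    '2015': 0.5
    '2016': 0.5
    '2017': 0.5
  pneumonia_intv_b:
    '2013': 0.5
    '2014': 0.5
    '2015': 0.5
    '2016': 0.5
    '2017': 0.5
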
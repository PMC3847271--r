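- id: diarrhea_vaccine_1
  name: diarrhea vaccine (first)
  category: PREVENTIVE
  stage_order: 4
  effects:
  - cause: diarrhea
    band: M1_5
    efficacy: 0.5
- id: diarrhea_vaccine_2
  name: diarrhea vaccine (second)
  category: PREVENTIVE
  stage_order: 4
  effects:
  - cause: diarrhea
    band: M1_5
    efficacy: 0.5
- id: pneumonia_intv_a
  name: pneumonia intervention A
  category: PREVENTIVE
  stage_order: 4
  effects:
  - cause: pneumonia
    band: M1_5
    efficacy: 0.4
- id: pneumonia_intv_b
  name: pneumonia intervention B
  category: PREVENTIVE
  stage_order: 4
  effects:
  - cause: pneumonia
    band: M1_5
    efficacy: 0.5
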
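roster:
- id: Wa
  name: Walter
  sex: male
  age_class: adult
  subgroup: A
  mother: .na.character
  father: .na.character
- id: To
  name: Toba
  sex: female
  age_class: adult
  subgroup: A
  mother: .na.character
  father: .na.character
- id: Ta
  name: Tao
  sex: female
  age_class: semi-dependent immature
  subgroup: A
  mother: To
  father: Wa
- id: Ei
  name: Eirina
  sex: female
  age_class: dependent immature
  subgroup: A
  mother: To
  father: Wa
- id: Su
  name: Suma
  sex: female
  age_class: adult
  subgroup: B
  mother: .na.character
  father: .na.character
- id: Dm
  name: Djamuna
  sex: female
  age_class: adult
  subgroup: B
  mother: .na.character
  father: .na.character
calendar:
- date: '2020-06-01'
  start_s: 28800.0
  duration_h: 3.0
  condition: outdoor
- date: '2020-06-02'
  start_s: 28800.0
  duration_h: 3.0
  condition: outdoor
- date: '2020-06-03'
  start_s: 28800.0
  duration_h: 3.0
  condition: indoor
- date: '2020-06-04'
  start_s: 28800.0
  duration_h: 3.0
  condition: indoor
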
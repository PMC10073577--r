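included:
  nervous:
  - Q00
  - Q01
  - Q02
  - Q03
  - Q04
  - Q05
  - Q06
  - Q07
  eye_ear_face_neck:
  - Q10
  - Q11
  - Q12
  - Q13
  - Q14
  - Q15
  - Q16
  - Q17
  - Q18
  circulatory:
  - Q20
  - Q21
  - Q22
  - Q23
  - Q24
  - Q25
  - Q26
  - Q27
  - Q28
  respiratory:
  - Q30
  - Q31
  - Q32
  - Q33
  - Q34
  cleft_lip_palate:
  - Q35
  - Q36
  - Q37
  digestive:
  - Q38
  - Q39
  - Q40
  - Q41
  - Q42
  - Q43
  - Q44
  - Q45
  genital:
  - Q50
  - Q51
  - Q52
  - Q54
  - Q55
  - Q56
  urinary:
  - Q60
  - Q61
  - Q62
  - Q63
  - Q64
  musculoskeletal:
  - Q65
  - Q66
  - Q67
  - Q68
  - Q69
  - Q70
  - Q71
  - Q72
  - Q73
  - Q74
  - Q75
  - Q76
  - Q77
  - Q78
  - Q79
  other:
  - Q80
  - Q81
  - Q82
  - Q83
  - Q84
  - Q85
  - Q86
  - Q87
  - Q88
  - Q89
excluded_minor:
- Q10.4
- Q10.5
- Q17
- Q18.0
- Q18.1
- Q18.2
- Q27.0
- Q38.1
- Q40.1
- Q53
- Q62.5
- Q65.3
- Q65.4
- Q65.5
- Q65.6
- Q66
- Q67
- Q69
- Q70
- Q82.5
- Q83.2
- Q84
chromosomal:
- Q90
- Q91
- Q92
- Q93
- Q94
- Q95
- Q96
- Q97
- Q98
- Q99
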
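schema: cnmpk-scenario-1
group: OC
dosing:
  dose: 1500.0
  infusion_duration: 90.0
  Q_liver: 20.7
  V_liver: 24.1
  t_end: 7200.0
  n_bile_transit: 1
parameters:
- id: 1
  name: Kp_liver_CPT11
  unit: '-'
  min: 0.1
  max: 10.0
- id: 2
  name: Kp_liver_SN38
  unit: '-'
  min: 0.1
  max: 10.0
- id: 3
  name: Kp_liver_SN38G
  unit: '-'
  min: 0.1
  max: 10.0
- id: 4
  name: Kp_liver_NPC
  unit: '-'
  min: 0.1
  max: 10.0
- id: 5
  name: Kp_liver_APC
  unit: '-'
  min: 0.1
  max: 10.0
- id: 6
  name: CL_r_CPT11
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 7
  name: CL_r_SN38
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 8
  name: CL_r_SN38G
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 9
  name: CL_r_NPC
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 10
  name: CL_r_APC
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 11
  name: CL_bile_CPT11
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 12
  name: CL_bile_SN38
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 13
  name: CL_bile_SN38G
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 14
  name: CL_bile_NPC
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 15
  name: CL_bile_APC
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 16
  name: CL_CES_1
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 17
  name: CL_CES_2
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 18
  name: CL_3A4_1
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 19
  name: CL_3A4_2
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 20
  name: CL_UGT
  unit: ml/min/kg
  min: 1.0
  max: 100.0
- id: 21
  name: k_feces_CPT11
  unit: /min
  min: 0.001
  max: 0.1
- id: 22
  name: k_feces_SN38
  unit: /min
  min: 0.001
  max: 0.1
- id: 23
  name: k_feces_SN38G
  unit: /min
  min: 0.001
  max: 0.1
- id: 24
  name: k_feces_NPC
  unit: /min
  min: 0.001
  max: 0.1
- id: 25
  name: k_feces_APC
  unit: /min
  min: 0.001
  max: 0.1
- id: 26
  name: k_a_CPT11
  unit: /min
  min: 0.001
  max: 0.1
- id: 27
  name: k_a_SN38
  unit: /min
  min: 0.001
  max: 0.1
- id: 28
  name: k_a_SN38G
  unit: /min
  min: 0.001
  max: 0.1
- id: 29
  name: k_a_NPC
  unit: /min
  min: 0.001
  max: 0.1
- id: 30
  name: k_a_APC
  unit: /min
  min: 0.001
  max: 0.1
- id: 31
  name: k_LI_CPT11
  unit: /min
  min: 0.001
  max: 0.1
- id: 32
  name: k_LI_SN38
  unit: /min
  min: 0.001
  max: 0.1
- id: 33
  name: k_LI_SN38G
  unit: /min
  min: 0.001
  max: 0.1
- id: 34
  name: k_LI_NPC
  unit: /min
  min: 0.001
  max: 0.1
- id: 35
  name: k_LI_APC
  unit: /min
  min: 0.001
  max: 0.1
- id: 36
  name: k_transit_CPT11
  unit: /min
  min: 0.001
  max: 0.1
- id: 37
  name: k_transit_SN38
  unit: /min
  min: 0.001
  max: 0.1
- id: 38
  name: k_transit_SN38G
  unit: /min
  min: 0.001
  max: 0.1
- id: 39
  name: k_transit_NPC
  unit: /min
  min: 0.001
  max: 0.1
- id: 40
  name: k_transit_APC
  unit: /min
  min: 0.001
  max: 0.1
- id: 41
  name: CL_12_CPT11
  unit: ml/min
  min: 1.0
  max: 100.0
- id: 42
  name: CL_12_SN38
  unit: ml/min
  min: 1.0
  max: 100.0
- id: 43
  name: CL_12_SN38G
  unit: ml/min
  min: 1.0
  max: 100.0
- id: 44
  name: CL_12_NPC
  unit: ml/min
  min: 1.0
  max: 100.0
- id: 45
  name: CL_12_APC
  unit: ml/min
  min: 1.0
  max: 100.0
- id: 46
  name: k_21_CPT11
  unit: /min
  min: 0.1
  max: 10.0
- id: 47
  name: k_21_SN38
  unit: /min
  min: 0.1
  max: 10.0
- id: 48
  name: k_21_SN38G
  unit: /min
  min: 0.1
  max: 10.0
- id: 49
  name: k_21_NPC
  unit: /min
  min: 0.1
  max: 10.0
- id: 50
  name: k_21_APC
  unit: /min
  min: 0.1
  max: 10.0
- id: 51
  name: V_rapid_CPT11
  unit: ml/kg
  min: 10.0
  max: 1000.0
- id: 52
  name: V_rapid_SN38
  unit: ml/kg
  min: 10.0
  max: 1000.0
- id: 53
  name: V_rapid_SN38G
  unit: ml/kg
  min: 10.0
  max: 1000.0
- id: 54
  name: V_rapid_NPC
  unit: ml/kg
  min: 10.0
  max: 1000.0
- id: 55
  name: V_rapid_APC
  unit: ml/kg
  min: 10.0
  max: 1000.0
- id: 56
  name: r_Ttube
  unit: '-'
  fixed: yes
  value: 0.0
objectives:
- id: 1
  name: urine_CPT11
  value: 427.0
- id: 2
  name: urine_SN38
  value: 8.2
- id: 3
  name: urine_SN38G
  value: 57.6
- id: 4
  name: urine_NPC
  value: 2.67
- id: 5
  name: urine_APC
  value: 42.5
- id: 6
  name: feces_CPT11
  value: 616.0
- id: 7
  name: feces_SN38_SN38G
  value: 162.0
- id: 8
  name: feces_NPC
  value: 25.9
- id: 9
  name: feces_APC
  value: 158.0
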
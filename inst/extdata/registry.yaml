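families:
- name: ABN
  donor_lifetime_0_ns: 1.6
  donor_brightness_0: 0.31
- name: AB_skN
  donor_lifetime_0_ns: 1.25
  donor_brightness_0: 0.26
- name: A_cBN
  donor_lifetime_0_ns: 1.07
  donor_brightness_0: 0.4
- name: AB_inN
  donor_lifetime_0_ns: 1.51
  donor_brightness_0: 0.56
constructs:
- label: AB6
  family: ABN
  'N': 6
- label: AB7
  family: ABN
  'N': 7
- label: AB8
  family: ABN
  'N': 8
- label: AB9
  family: ABN
  'N': 9
- label: AB10
  family: ABN
  'N': 10
- label: AB11
  family: ABN
  'N': 11
- label: AB12
  family: ABN
  'N': 12
- label: AB13
  family: ABN
  'N': 13
- label: AB14
  family: ABN
  'N': 14
- label: AB15
  family: ABN
  'N': 15
- label: AB16
  family: ABN
  'N': 16
- label: AB17
  family: ABN
  'N': 17
- label: AB18
  family: ABN
  'N': 18
- label: AB19
  family: ABN
  'N': 19
- label: AB20
  family: ABN
  'N': 20
- label: AB_sk6
  family: AB_skN
  'N': 6
- label: AB_sk7
  family: AB_skN
  'N': 7
- label: AB_sk8
  family: AB_skN
  'N': 8
- label: AB_sk9
  family: AB_skN
  'N': 9
- label: AB_sk10
  family: AB_skN
  'N': 10
- label: AB_sk11
  family: AB_skN
  'N': 11
- label: AB_sk12
  family: AB_skN
  'N': 12
- label: AB_sk13
  family: AB_skN
  'N': 13
- label: A_cB6
  family: A_cBN
  'N': 6
- label: A_cB7
  family: A_cBN
  'N': 7
- label: A_cB8
  family: A_cBN
  'N': 8
- label: A_cB9
  family: A_cBN
  'N': 9
- label: A_cB10
  family: A_cBN
  'N': 10
- label: A_cB11
  family: A_cBN
  'N': 11
- label: A_cB12
  family: A_cBN
  'N': 12
- label: A_cB13
  family: A_cBN
  'N': 13
- label: A_cB14
  family: A_cBN
  'N': 14
- label: AB_in6
  family: AB_inN
  'N': 6
- label: AB_in7
  family: AB_inN
  'N': 7
- label: AB_in8
  family: AB_inN
  'N': 8
- label: AB_in9
  family: AB_inN
  'N': 9
- label: AB_in10
  family: AB_inN
  'N': 10
- label: AB_in11
  family: AB_inN
  'N': 11
- label: AB_in12
  family: AB_inN
  'N': 12
- label: AB_in13
  family: AB_inN
  'N': 13
- label: AB_in14
  family: AB_inN
  'N': 14
fret_model:
  R0_nm: 5.4
  rise_nm: 0.34
defaults:
  hydrodynamic_radius_nm: 2.0
  bound_radius_multiplier: 3.0
  acceptor_brightness_scale: 1.0
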
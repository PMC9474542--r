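atoms:
- name: N1
  element: 'N'
- name: N2
  element: 'N'
- name: C3
  element: C
- name: C4
  element: C
- name: C5
  element: C
- name: HN1
  element: H
- name: CB1
  element: C
- name: CB2
  element: C
- name: CB3
  element: C
- name: CB4
  element: C
- name: CB5
  element: C
- name: CB6
  element: C
- name: O1
  element: O
- name: O2
  element: O
- name: CM
  element: C
- name: CP1
  element: C
- name: CP2
  element: C
- name: CP3
  element: C
- name: CP4
  element: C
- name: CP5
  element: C
- name: CP6
  element: C
- name: BR
  element: Br
groups:
  pyrazole_ring:
  - N1
  - N2
  - C3
  - C4
  - C5
  pyrazole_N:
  - N1
  - N2
  benzodioxole_ring:
  - CB1
  - CB2
  - CB3
  - CB4
  - CB5
  - CB6
  benzodioxole_O:
  - O1
  - O2
  bromophenyl_ring:
  - CP1
  - CP2
  - CP3
  - CP4
  - CP5
  - CP6
  halogen:
  - BR
  halogen_bonded_carbon:
  - CP3
coords_nm:
- - -0.0685
  - -0.0942822
  - 0.0
- - 0.0685
  - -0.0942822
  - 0.0
- - 0.1108353
  - 0.0360126
  - 0.0
- - 7.1359655e-18
  - 1.1653916e-01
  - 0.0e+00
- - -0.1108353
  - 0.0360126
  - 0.0
- - -0.1278663
  - -0.1759929
  - 0.0
- - 0.2515917
  - 0.0817471
  - 0.0
- - 0.3548888
  - -0.0112621
  - 0.0
- - 0.4870857
  - 0.0316913
  - 0.0
- - 0.5159854
  - 0.1676538
  - 0.0
- - 0.4126883
  - 0.260663
  - 0.0
- - 0.2804914
  - 0.2177096
  - 0.0
- - 0.6267881
  - 0.2667435
  - 0.0
- - 0.4595053
  - 0.3366277
  - 0.0
- - 0.7252178
  - 0.2356376
  - 0.0
- - -0.2515917
  - 0.0817471
  - 0.0
- - -0.2804914
  - 0.2177096
  - 0.0
- - -0.4126883
  - 0.260663
  - 0.0
- - -0.5159854
  - 0.1676538
  - 0.0
- - -0.4870857
  - 0.0316913
  - 0.0
- - -0.3548888
  - -0.0112621
  - 0.0
- - -0.4521915
  - 0.446511
  - 0.0
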
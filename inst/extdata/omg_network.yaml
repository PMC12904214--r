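# Default network for suspected ocular myasthenia gravis (OMG).
# Age and sex are roots; OMG depends on sex; the AChR antibody test depends
# on OMG and age (its sensitivity is strongly age-dependent); every other
# test or sign depends on OMG alone.
outcome: omg
positive_state: positive
variables:
- name: age
  states: ["18-50", "50-70", "70+"]
  parents: []
- name: sex
  states: [male, female]
  parents: []
- name: omg
  states: [negative, positive]
  parents: [sex]
- name: diplopia
  states: [negative, positive]
  parents: [omg]
- name: ptosis
  states: [negative, positive]
  parents: [omg]
- name: achr
  states: [negative, positive]
  parents: [omg, age]
- name: upgaze
  states: [negative, positive]
  parents: [omg]
- name: ice
  states: [negative, positive]
  parents: [omg]
- name: besinger
  states: [-1to1, 1to4, 4to8, 8to24]
  parents: [omg]
- name: edrophonium
  states: [negative, positive]
  parents: [omg]
- name: rns
  states: [negative, positive]
  parents: [omg]
- name: sfemg
  states: [negative, positive]
  parents: [omg]
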
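# Single-wolf-source model: the dog clade diverged most recently from
# the Israeli wolf lineage, with the remaining wolves branching off in a
# near-star fashion. Figure-only values carry the same documented
# defaults as fig5a.yaml.
name: isw_source
generation_time: 3
populations:
  - {name: BOX, parent: ancDOG1, ne: 2000}
  - {name: BSJ, parent: ancDOG1, ne: 2000}
  - {name: DNG, parent: ancDOG, ne: 2000}
  - {name: ISW, parent: ancDIS, ne: 10000}
  - {name: CRW, parent: ancW1, ne: 10000}
  - {name: CHW, parent: ancDW, ne: 10000}
  - {name: GLJ, parent: root, ne: 10000}
  - {name: ancDOG1, parent: ancDOG, ne: 2000}
  - {name: ancDOG, parent: ancDIS, ne: 2000}
  - {name: ancDIS, parent: ancW1, ne: 12600}
  - {name: ancW1, parent: ancDW, ne: 12600}
  - {name: ancDW, parent: root, ne: 45000}
  - {name: root, ne: 45000}
splits:
  ancDOG1: 12100
  ancDOG: 12800
  ancDIS: 13300
  ancW1: 13600
  ancDW: 14900
  root: 398000
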
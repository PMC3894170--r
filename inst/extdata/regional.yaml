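# Regional-domestication model: each dog lineage is sister to the wolf
# from its geographic region (Basenji-Israeli wolf, Boxer-Croatian wolf,
# Dingo-Chinese wolf). One of the three possible orderings of the
# regional ancestors is used. Figure-only values carry the same
# documented defaults as fig5a.yaml.
name: regional
generation_time: 3
populations:
  - {name: BOX, parent: ancEUR, ne: 2000}
  - {name: CRW, parent: ancEUR, ne: 10000}
  - {name: BSJ, parent: ancMEA, ne: 2000}
  - {name: ISW, parent: ancMEA, ne: 10000}
  - {name: DNG, parent: ancEAS, ne: 2000}
  - {name: CHW, parent: ancEAS, ne: 10000}
  - {name: GLJ, parent: root, ne: 10000}
  - {name: ancEUR, parent: ancWest, ne: 12600}
  - {name: ancMEA, parent: ancWest, ne: 12600}
  - {name: ancEAS, parent: ancDW, ne: 12600}
  - {name: ancWest, parent: ancDW, ne: 12600}
  - {name: ancDW, parent: root, ne: 45000}
  - {name: root, ne: 45000}
splits:
  ancEUR: 12800
  ancMEA: 12800
  ancEAS: 12800
  ancWest: 13400
  ancDW: 14900
  root: 398000
migration_bands:
  - {source: BSJ, target: BOX, m_tot: 0.05}
  - {source: BSJ, target: DNG, m_tot: 0.05}
  - {source: CRW, target: ISW, m_tot: 0.05}
  - {source: CRW, target: CHW, m_tot: 0.05}
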
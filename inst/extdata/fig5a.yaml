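# Seven-canid demographic model: dog/wolf reciprocal monophyly.
#
# Leaves: BOX Boxer, BSJ Basenji, DNG Dingo, ISW Israeli wolf,
# CRW Croatian wolf, CHW Chinese wolf, GLJ golden jackal (outgroup).
#
# Split times (years) and the ancestral effective sizes of the dog/wolf
# ancestor (45,000), the dog ancestor (2,000) and the wolf ancestor
# (12,600) are the inferred point estimates; the remaining values are
# figure-only and carry documented defaults the user may override:
#   - terminal wolf Ne 10,000 (present-day wolf estimates 10,000-17,000)
#   - terminal dog Ne 2,000 (recent dog lineages below 2,000)
#   - golden jackal terminal Ne 10,000
#   - root (canid + jackal ancestor) Ne 45,000
#   - inner wolf split 13,300 y (wolf splits tightly clustered at 13,400;
#     strict root-ward ordering requires distinct values)
#   - migration band totals m_tot 0.05 (nearly all inferred totals < 10%)
# Band direction is forward in time (source -> target).
name: fig5a
generation_time: 3
populations:
  - {name: BOX, parent: ancDOG1, ne: 2000}
  - {name: BSJ, parent: ancDOG1, ne: 2000}
  - {name: DNG, parent: ancDOG, ne: 2000}
  - {name: ISW, parent: ancWLF1, ne: 10000}
  - {name: CRW, parent: ancWLF1, ne: 10000}
  - {name: CHW, parent: ancWLF, ne: 10000}
  - {name: GLJ, parent: root, ne: 10000}
  - {name: ancDOG1, parent: ancDOG, ne: 2000}
  - {name: ancDOG, parent: ancDW, ne: 2000}
  - {name: ancWLF1, parent: ancWLF, ne: 12600}
  - {name: ancWLF, parent: ancDW, ne: 12600}
  - {name: ancDW, parent: root, ne: 45000}
  - {name: root, ne: 45000}
splits:
  ancDOG1: 12100
  ancDOG: 12800
  ancWLF1: 13300
  ancWLF: 13400
  ancDW: 14900
  root: 398000
migration_bands:
  - {source: ISW, target: BSJ, m_tot: 0.05}
  - {source: BSJ, target: ISW, m_tot: 0.05}
  - {source: CHW, target: DNG, m_tot: 0.05}
  - {source: DNG, target: CHW, m_tot: 0.05}
  - {source: GLJ, target: ISW, m_tot: 0.05}
  - {source: GLJ, target: ancDW, m_tot: 0.05}
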
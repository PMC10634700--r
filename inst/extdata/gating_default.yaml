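# Default exclusive gating hierarchy: 23 terminal cell lineages/states,
# 18 of them T cell states. Siblings are evaluated in listed order and the
# first matching gate wins, so later siblings act as residuals of earlier
# ones. A gate matches when every require_positive marker is positive,
# every require_negative marker is negative, and (when present) at least
# one require_any marker is positive.
#
# The canonical T state predicates (T_NAIVE .. T_TEX) are package defaults
# over the panel markers; they are configuration, not code, and may be
# overridden by supplying a different file to load_gating_config().
schema_version: 1
panel:
  - CD3
  - CD8
  - FOXP3
  - CD20
  - CD68
  - PanCK
  - aSMA
  - TOX1
  - TIM3
  - TCF-1
  - CD38
  - PD-1
  - EOMES
  - CD39
  - CD44
  - LAG-3
  - T-BET
  - Ki-67
  - GrzB
nodes:
  - name: root
    parent: ~

  # ---- T cell branch -------------------------------------------------
  - name: T cell
    parent: root
    require_positive: [CD3]

  - name: CD8 T cell
    parent: T cell
    require_positive: [CD8]

  - name: T_NAIVE
    parent: CD8 T cell
    require_positive: [TCF-1]
    require_negative: [CD44, PD-1, TOX1, EOMES, TIM3, LAG-3]
    terminal: true
    t_state: true
  - name: T_EFF
    parent: CD8 T cell
    require_positive: [CD44, T-BET]
    require_negative: [TCF-1, PD-1, TIM3, LAG-3, TOX1, EOMES]
    terminal: true
    t_state: true
  - name: T_EM
    parent: CD8 T cell
    require_positive: [CD44, TCF-1, T-BET]
    terminal: true
    t_state: true
  - name: T_EMRA
    parent: CD8 T cell
    require_positive: [T-BET, EOMES]
    require_negative: [CD44]
    terminal: true
    t_state: true
  - name: T_EX
    parent: CD8 T cell
    require_positive: [PD-1]
    require_negative: [TOX1]
    require_any: [TIM3, LAG-3]
    terminal: true
    t_state: true
  - name: T_TEX
    parent: CD8 T cell
    require_positive: [PD-1]
    require_any: [TOX1, EOMES]
    terminal: true
    t_state: true
  - name: CD44+ T_OTHER
    parent: CD8 T cell
    require_positive: [CD44]
    terminal: true
    t_state: true
  - name: CD44- T_OTHER
    parent: CD8 T cell
    require_negative: [CD44]
    terminal: true
    t_state: true

  # ---- CD3+ CD8- (CD4) branch ---------------------------------------
  - name: CD4 T cell
    parent: T cell
    require_negative: [CD8]

  - name: T_REG
    parent: CD4 T cell
    require_positive: [FOXP3]
  - name: T-BET+ T_REG
    parent: T_REG
    require_positive: [T-BET]
    terminal: true
    t_state: true
    treg: true
  - name: mT_REG
    parent: T_REG
    require_positive: [CD44]
    terminal: true
    t_state: true
    treg: true
  - name: Naive T_REG
    parent: T_REG
    require_negative: [CD44]
    terminal: true
    t_state: true
    treg: true

  - name: Th1
    parent: CD4 T cell
    require_positive: [T-BET]
    require_negative: [FOXP3]
  - name: Th1 T_EFF
    parent: Th1
    require_positive: [CD44]
    require_negative: [TCF-1, PD-1, TIM3, LAG-3, TOX1, EOMES]
    terminal: true
    t_state: true
  - name: Th1 T_EM
    parent: Th1
    require_positive: [CD44, TCF-1]
    terminal: true
    t_state: true
  - name: Th1 T_EMRA
    parent: Th1
    require_positive: [EOMES]
    require_negative: [CD44]
    terminal: true
    t_state: true
  - name: CD44+ Th1 T_OTHER
    parent: Th1
    require_positive: [CD44]
    terminal: true
    t_state: true
  - name: CD44- Th1 T_OTHER
    parent: Th1
    require_negative: [CD44]
    terminal: true
    t_state: true

  - name: Th
    parent: CD4 T cell
    require_negative: [FOXP3, T-BET]
  - name: CD44+ Th
    parent: Th
    require_positive: [CD44]
    terminal: true
    t_state: true
  - name: CD44- Th
    parent: Th
    require_negative: [CD44]
    terminal: true
    t_state: true

  # ---- non-T branch --------------------------------------------------
  - name: non-T
    parent: root
    require_negative: [CD3]
  - name: Neoplastic epithelial
    parent: non-T
    require_positive: [PanCK]
    terminal: true
  - name: Mesenchymal
    parent: non-T
    require_positive: [aSMA]
    terminal: true
  - name: Myeloid
    parent: non-T
    require_positive: [CD68]
    terminal: true
  - name: B cell
    parent: non-T
    require_positive: [CD20]
    terminal: true
  - name: Other
    parent: non-T
    terminal: true
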
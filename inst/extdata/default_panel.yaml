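markers:
- name: panCK
  threshold: 1.2
  role: epithelial/tumor lineage
- name: CD45
  threshold: 1.0
  role: pan-leukocyte
- name: CD3
  threshold: 1.0
  role: T cell
- name: CD4
  threshold: 0.9
  role: helper T
- name: CD8
  threshold: 1.0
  role: cytotoxic T
- name: FOXP3
  threshold: 0.8
  role: Treg transcription factor
- name: Tbet
  threshold: 0.8
  role: Th1 transcription factor
- name: CD39
  threshold: 0.9
  role: ectonucleotidase, Trm proxy
- name: CD103
  threshold: 0.9
  role: integrin alphaE, Trm proxy
- name: CD56
  threshold: 0.8
  role: NK lineage
- name: CD20
  threshold: 1.0
  role: B lineage
- name: CD68
  threshold: 1.1
  role: macrophage
- name: CD163
  threshold: 0.9
  role: M2 macrophage
- name: CD206
  threshold: 0.9
  role: mannose receptor, M2 macrophage
- name: CD11c
  threshold: 0.9
  role: dendritic cell
- name: CD11b
  threshold: 1.0
  role: myeloid integrin
- name: CD33
  threshold: 0.8
  role: myeloid progenitor
- name: HLADR
  threshold: 1.0
  role: MHC class II
- name: FAP
  threshold: 1.0
  role: fibroblast activation protein (CAF)
- name: aSMA
  threshold: 1.1
  role: smooth muscle actin
- name: CD31
  threshold: 0.9
  role: endothelial
- name: PD1
  threshold: 0.8
  role: checkpoint receptor
- name: PDL1
  threshold: 0.8
  role: checkpoint ligand
- name: LAG3
  threshold: 0.7
  role: checkpoint receptor
- name: TIM3
  threshold: 0.7
  role: checkpoint receptor
- name: TIGIT
  threshold: 0.7
  role: checkpoint receptor
- name: GZMB
  threshold: 0.8
  role: effector granzyme
- name: Ki67
  threshold: 0.9
  role: proliferation
- name: CD73
  threshold: 0.9
  role: ecto-5'-nucleotidase
gating:
- label: cancer
  require:
    panCK: +
    CD45: '-'
- label: leukocyte_other
  require:
    CD45: +
  children:
  - label: t_other
    require:
      CD3: +
    children:
    - label: nkt
      require:
        CD56: +
    - label: cd8_t
      require:
        CD8: +
      children:
      - label: cd8_trm
        require:
          CD39: +
          CD103: +
    - label: cd4_t
      require:
        CD4: +
      children:
      - label: treg
        require:
          FOXP3: +
      - label: th1
        require:
          Tbet: +
          FOXP3: '-'
  - label: nk
    require:
      CD56: +
  - label: b_cell
    require:
      CD20: +
  - label: tam_other
    require:
      CD68: +
    children:
    - label: tam_m2_cd206
      require:
        CD206: +
    - label: tam_m2_cd163
      require:
        CD163: +
        CD206: '-'
    - label: tam_m1
      require:
        HLADR: +
        CD163: '-'
        CD206: '-'
  - label: dc
    require:
      CD68: '-'
      CD11c: +
      HLADR: +
  - label: mdsc
    require:
      CD11b: +
      CD33: +
      HLADR: '-'
- label: caf
  require:
    panCK: '-'
    CD45: '-'
    FAP: +
- label: stromal_other
  require:
    panCK: '-'
    CD45: '-'
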
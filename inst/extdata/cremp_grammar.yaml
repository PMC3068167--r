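specs:
- label: a
  internal_gaps:
  - 4
  - 5
  - 8
  tail: 6
  gap_tolerance: 1
  max_tail_insert: 64
- label: b
  internal_gaps:
  - 4
  - 5
  - 8
  tail: 11
  gap_tolerance: 1
  max_tail_insert: 64
catalogue:
- position: 3
  residue: D
  scope: shared
- position: 8
  residue: K
  scope: shared
- position: 9
  residue: G
  scope: shared
- position: 17
  residue: G
  scope: shared
- position: 19
  residue: P
  scope: shared
- position: 7
  residue: P
  scope: a
- position: 26
  residue: P
  scope: a
- position: 25
  residue: K
  scope: b
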
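# Reference amino-acid compositions (percent) for Euclidean comparison.
# Components follow the 17-key convention: 20 standard residues minus Trp,
# with D+N merged as DN and E+Q merged as EQ. Entries from acid-hydrolysis
# literature may carry Hyl/Hyp, which are added to K and P at load.
#
# The eggshell-membrane (esm) entry pins only the two components reported
# in the primary literature (Gly 9.5%, Cys 10.1%); the remaining components
# must be supplied by the user from their own literature average before
# distance ranking. collagen/keratin/elastin entries are intentionally left
# for the user to compute from their preferred accessions; this file only
# fixes the format.
esm:
  note: "partial reference: only Gly and Cys are pinned"
  G: 9.5
  C: 10.1
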
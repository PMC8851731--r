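# Real reference inputs (user-supplied)

Two validation checks in `tests/testthat/test-acceptance.R` compare package
output against real reference data that cannot be redistributed here. To
activate them, place in this directory:

- `GSE36002_series_matrix.txt` — the GEO series-matrix file of the
  HumanMethylation27 osteosarcoma cell-line / normal-bone cohort
  (accession GSE36002).
- `GSE36002_groups.tsv` — tab-separated `sample<TAB>group` mapping each GSM
  sample id to `cell_line` or `bone`.
- `hg19_chr8_41654876_41655984.fa` — FASTA of the hg19 sequence at
  chr8:41654876-41655984 (1-based inclusive display coordinates; 1109 bp).

Without these files the two checks report as failures, so their status is
never silently hidden.
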
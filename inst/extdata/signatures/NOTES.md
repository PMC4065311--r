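# Reference signature fixtures

Three published cross-study peptide signatures from the two-study MRL/lpr
immunosignaturing experiments, transcribed verbatim:

- `diagnostic_lupus.tsv` - 58 peptides diagnostic of lupus (4-month MRL/lpr
  vs 4-month C3H/HeJ, mean + 1.5 SD cutoff, shared by both studies).
- `diagnostic_behavior.tsv` - 39 peptides diagnostic of high-floater
  behavior in the forced swim test.
- `predictive_lupus.tsv` - 18 peptides predictive of lupus (4-month MRL/mp
  at mean + 0.25 SD; 1.5-month MRL/lpr at mean + 1.5 SD).

Columns: `sequence`, the two studies' binding ratios, and logical
cross-membership flags. Rows are sorted lexicographically by sequence.

## Known printed inconsistencies (quarantined)

The printed cross-membership check marks disagree with the printed sequence
sets in exactly two places; both rows are transcribed as printed and are
excluded from flag-consistency checks:

1. `LAFAWKPDPWQSLVTKFGSC` appears in both the diagnostic-lupus and
   diagnostic-behavior sequence sets, but the diagnostic-behavior table does
   not flag it as "in common with diagnostic peptides of lupus".
2. `KIWAMRKPRYQYWNQPAGSC` (predictive-lupus table) is flagged as "in common
   with diagnostic peptides of lupus" but does not appear in the
   diagnostic-lupus sequence set.

All other flags are consistent with set membership computed from the
sequences. Flags referring to the 96-peptide behavior-predictive set cannot
be checked: that set was not published.
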
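# Curated domain reference data (not redistributed)

The reference checks in the test suite rebuild the AT- and A-domain
substrate libraries from the curated sets of experimentally validated
domain sequences (167 non-redundant AT domains over 8 modelled substrates;
571 non-redundant A domains over 39 modelled substrates). Those sequence
collections are not redistributable with this package. To run the
reference checks, export them from the curated distribution into this
directory as plain text:

- `at_alignment.fasta` / `a_alignment.fasta` — the trimmed, reduced,
  aligned non-redundant domain sequences (aligned FASTA, `-` gaps).
- `at_annotation.tsv` / `a_annotation.tsv` — tab-separated with header
  `seq_id  substrate  domain_type  redundant`.
- `at_partitions.tsv` / `a_partitions.tsv` — the ensemble subdivision used
  for well-represented substrates, tab-separated with header
  `seq_id  substrate  part_index`.

All ids must match between the three files of a domain type.
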
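# External reference sequences (not distributed)

The package never downloads sequences. To run the reference-sequence checks
in the test suite, fetch the records below (e.g. with NCBI `efetch`), trim
to the stated regions, and save them here as plain FASTA:

| file                   | accession      | region      |
|------------------------|----------------|-------------|
| `psolanasi_tsa2.fasta` | HAFJ01050538.1 | 1021-1303   |
| `wenling2.fasta`       | WLJQ104117 (as printed) | IGR + ORF2 start |
| `n_ov_008.fasta`       | KY130493       | IGR + ORF2 start (approx. 4786-5071) |

Example:

    efetch -db nuccore -id HAFJ01050538.1 -format fasta \
      -seq_start 1021 -seq_stop 1303 > psolanasi_tsa2.fasta

Without these files the corresponding test block reports the sequences as
unavailable; all other tests are self-contained.
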
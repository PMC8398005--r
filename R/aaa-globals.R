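## Shared column and category constants (collated first).

COVARIATE_COLUMNS <- c("WT", "SEX", "AGE", "DISEASE", "MTX", "IMM", "ADA",
                       "ALB", "HBI", "PERIOD")
DISEASES <- c("Crohn", "UC", "AS", "PsA", "RA")
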
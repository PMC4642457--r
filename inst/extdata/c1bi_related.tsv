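# Control-region haplotypes closely related to, or members of, the C1b*i*
# clade. Variants are relative to the C1b root motif (use rebase_haplotypes()
# for rCRS-relative sets); ranges are the published sequencing ranges.
sample_id	population	country	period	range	variants
Aconcagua	Inca	Argentina (Mendoza)	AD 1480	16024-16569	16124
AymaraPE1	Aymara	Peru (Apurimac)	modern	16024-16383	16124 16362
Wari1	Post-Wari	Peru (Ayacucho)	AD 1000-1450	16011-16382	16124 16189 16222 16316
AymaraBO1	Aymara	Bolivia (La Paz)	modern	16024-16383	16124 16183C 16189
AymaraBO2	Aymara	Bolivia (La Paz)	modern	16024-16383	16124 16183C 16189
AymaraBO3	Aymara	Bolivia (La Paz)	modern	16024-16383	16124 16183C 16189
BolivianBO1	Bolivian	Bolivia (Cochabamba)	modern	16024-16569	16111 16124
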
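# GenBank accession ranges of the published ruminant DRB exon-2 allele
# panels analyzed by this package's reference workflow. Fetching is left to
# the user (no network code ships in the analysis path); download, align,
# trim to the common 234-bp exon-2 window, then run the pipeline.
# NOTE an erratum in the published buffalo list: "AF3854473" carries one
# digit too many for a GenBank identifier and cannot be resolved with
# certainty; it is reproduced verbatim here, not guessed.
panel	accessions
Indian cattle (Bos indicus)	AF261953-AF261954; AF272862-AF272876; AF272878-AF272882
Buffalo (Bubalus bubalis)	AF3854473-AF385480; AF261955-AF261956; AF270653-AF270659; AF270661-AF270673
Sheep (Ovis aries)	AF126432-AF126441; Y10245-Y10249; U00204-U00219; U00221-U00225; U00227-U00237
Goat (Capra hircus)	AB008347-AB008362
Big horn sheep (Ovis canadensis)	AF324-AF324861
White-tailed deer (Odocoileus virginianus)	AF082161-AF082175
Red deer (Cervus elaphus)	U11101-U11108; U11110-U11116; U11118-U11119; U11121; U11212; U11213; U11215-U11218
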
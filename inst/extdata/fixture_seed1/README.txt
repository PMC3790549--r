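Frozen synthetic study fixture (master seed 1, default fixture_spec()).

Synthetic data: a pure-birth tree of 22 taxa with a simulated two-region
dispersal history, Mk-evolved male plumage characters (25 six-state colour
patches + 5 presence/absence traits), a female matrix derived from the male
one with baseline noise plus southern-regime state biases, and per-taxon
region/latitude metadata (degrees south).

The matching seven-locus alignment is not stored; regenerate the complete
bundle with plumevol::make_study_fixture(fixture_spec(seed = 1)). A test
pins these files to that regeneration, so they double as a determinism
check for the generator.
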
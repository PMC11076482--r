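# extdata

- `borane_library_transcription_stub.csv` — transcription stub for the
  published borane library. It lists the boranes that are identified by
  name in the study text (the 15 initially measured boranes, plus the
  B4b/B4c/B4e validation trio) with **all descriptor cells left empty**:
  the numeric LUMO / free-energy / deformation-energy / Mulliken-charge
  values are printed only in the publication's figures and supplementary
  tables and must be transcribed there by the user before the
  literature-reproduction workflows can run. Empty cells are explicit
  missing values in the library schema; nothing here is a guessed number.
- `experiments_model_reaction_stub.csv` — the single model-reaction
  outcome stated numerically in the study text (B1a: 50% yield, 5 mol%
  loading, 6 h, i.e. TOF = 1.67 1/h). Remaining experimental rows must
  likewise be transcribed from the published figures.

Synthetic example data are not shipped as files: generate them with
`sample_library()` / `sample_experiments()` (seeded, reproducible).
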
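# The default synthetic study and its summary are expensive enough to share:
# computed once per test run, at a fixed seed, and cached in this environment.
.studyCache <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.studyCache$ds))
    .studyCache$ds <- simulateStudy(synthConfig(seed = 104729))
  .studyCache$ds
}

defaultStudySummary <- function() {
  if (is.null(.studyCache$res))
    .studyCache$res <- summarizeStudy(defaultStudy())
  .studyCache$res
}
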
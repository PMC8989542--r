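# Shared fixtures: a small architecture for fast tests, random sequence
# generators, and a synthetic CTCF-like PWM.

tinyConfig <- function(inputLength = 50L) {
  irlstmConfig(inputLength = inputLength, stemFilters = 16L,
               branchFilters = 8L, lstmUnits = 8L)
}

# an untrained model with the tiny architecture (random weights are fine
# for contract tests: RC invariance, window semantics, serialization)
tinyModel <- function(seed = 7L, inputLength = 50L) {
  buildIRLSTM(tinyConfig(inputLength), seed = seed)
}

randomSeq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

randomSeqs <- function(n, L) vapply(seq_len(n), function(i) randomSeq(L),
                                    character(1))

# deterministic point-mass PWM spelling out a consensus
consensusPWM <- function(consensus) {
  W <- nchar(consensus)
  m <- matrix(0, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- strsplit(consensus, "")[[1]]
  m[cbind(match(ch, rownames(m)), seq_len(W))] <- 1
  m
}

syntheticCTCFPath <- function() {
  system.file("extdata", "synthetic_ctcf_like_19bp.jaspar",
              package = "DNAbendR")
}
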
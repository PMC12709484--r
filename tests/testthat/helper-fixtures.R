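# Shared fixtures, generated in code.

# classical level-4 Sierpinski carpet (81 x 81)
carpet4 <- function() make_carpet(b = 3, levels = 4)

# checkerboard 0/255 grayscale image
checkerboard <- function(n = 8) {
  matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0, 255L, 0L), n, n)
}

small_cohort <- function(severity, seeds, size = 96) {
  lapply(seeds, function(s) {
    make_pseudo_tissue(size = size, severity = severity, seed = s)
  })
}
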
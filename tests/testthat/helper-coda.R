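# random strictly positive composition
rand_comp <- function(D) closure(stats::rexp(D) + 1e-3)

# independent clr-based oracle for the Aitchison distance (kept separate
# from the package's implementation path, which goes through validation
# and zero replacement)
oracle_clr <- function(x) log(x) - mean(log(x))
oracle_dist <- function(x, y) sqrt(sum((oracle_clr(x) - oracle_clr(y))^2))

# direct evaluation of the pivot ILR definition, one line per coordinate
oracle_ilr <- function(x) {
  D <- length(x)
  vapply(seq_len(D - 1), function(d) {
    sqrt(d / (d + 1)) * log(prod(x[1:d])^(1 / d) / x[d + 1])
  }, numeric(1))
}

# small constant-composition series for degenerate-input tests
const_series <- function(parts, n = 30, start_year = 1990) {
  coda_series(start_year + 0:(n - 1),
              matrix(rep(parts, each = n), nrow = n))
}
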
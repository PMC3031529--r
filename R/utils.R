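# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure in their seed.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Connected components of a symmetric logical/binary matrix, by breadth-first
# search.  Returns an integer membership vector; components are numbered 1..k
# in order of their smallest member index.
bool_components <- function(M) {
  m <- nrow(M)
  if (m == 0L) return(integer(0))
  comp <- rep(NA_integer_, m)
  k <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(M[v, ] != 0 & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# Region letters: "A".."Z", then "AA", "AB", ... for the (rare) case of more
# than 26 regions.
region_letters <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  extra <- k - 26L
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS)[seq_len(extra)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
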
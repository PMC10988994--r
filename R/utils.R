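# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed, platform-stable RNG state
#'
#' Sets the Mersenne-Twister / Inversion / Rejection RNG combination before
#' evaluating `code`, and restores the caller's RNG state afterwards, so
#' simulation functions are reproducible without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_rng <- function(seed, code) {
  genv <- globalenv()
  has_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# Per-stage substream seeds derived from one global seed, kept well below
# 2^31 so they are valid R integer seeds.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, prs = 211L, mr = 307L,
               sensitivity = 401L, cea = 503L)
  stage <- match.arg(stage, names(offsets))
  as.integer((as.numeric(seed) %% 1000003) * 1000 + offsets[[stage]])
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, returned as 8 hex digits.
# Used only for provenance comments in output file headers.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor_dbl(h, b %% 256)
    lo <- h %% two16
    hi <- (h - lo) / two16
    h <- (lo * p + ((hi * p) %% two16) * two16) %% two32
  }
  format_hex32(h)
}

# bitwXor for doubles that may exceed .Machine$integer.max - 1 range safety
bitwXor_dbl <- function(a, b) {
  r <- 0
  bit <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + bit
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    bit <- bit * 2
  }
  r
}

format_hex32 <- function(h) {
  hi <- floor(h / 65536)
  lo <- h - hi * 65536
  sprintf("%04x%04x", hi, lo)
}

# shared critical value: the two-sided 95% normal quantile used throughout
# (interval construction and CI-to-SE back-conversion)
Z95 <- 1.96
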
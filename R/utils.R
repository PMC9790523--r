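# internal helpers: seeded evaluation, error conditions, small numerics

# gyromagnetic ratio of 1H, Hz per Tesla
.GAMMA_HZ_PER_T <- 42.5774688e6

# single-peak fat resonance offset relative to water, ppm (negative)
.FAT_PPM <- -3.4

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Classed stop() so callers can distinguish validation from runtime failures
#' @noRd
ldStop <- function(msg, class = "lgeDixon_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "lgeDixon_error")))
}

#' @noRd
ldAssert <- function(ok, msg, class = "lgeDixon_error") {
  if (!isTRUE(ok)) ldStop(msg, class = class)
}

#' Wrap x into (-period/2, period/2]
#' @noRd
wrapToRange <- function(x, period) {
  y <- (x + period / 2) %% period - period / 2
  y[y == -period / 2] <- period / 2
  y
}

#' md5 of an R object via canonical serialization (for provenance logs)
#' @noRd
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Default fat chemical-shift frequency (Hz) at a given field strength
#'
#' Single-peak fat model at -3.4 ppm relative to water; at 1.5 T this is
#' approximately -217 Hz.
#'
#' @param fieldStrength main field strength in Tesla.
#' @return Frequency offset in Hz (negative).
#' @examples
#' fatShiftHz(1.5)
#' @export
fatShiftHz <- function(fieldStrength) {
  .FAT_PPM * 1e-6 * .GAMMA_HZ_PER_T * fieldStrength
}

#' Inversion-recovery weighting of longitudinal magnetization
#'
#' Idealized weighting `A(T1, TI) = 1 - 2 exp(-TI/T1)` applied to every
#' tissue by the acquisition simulator. `A` crosses zero when
#' `TI = T1 * log(2)`: a tissue is nulled when the inversion time matches
#' that product, which is how the LGE protocol suppresses healthy
#' myocardium (post-contrast T1 about 500 ms) while leaving
#' gadolinium-retaining scar and short-T1 fat (280 ms) visible.
#'
#' @param t1 longitudinal relaxation time(s), ms. May be a vector or array.
#' @param ti inversion time, ms.
#' @return Signed weighting, same shape as `t1`.
#' @examples
#' inversionWeight(500 / log(2), 500) # analytic null
#' @export
inversionWeight <- function(t1, ti) {
  ldAssert(all(t1 > 0), "t1 must be positive")
  ldAssert(is.numeric(ti) && length(ti) == 1L && ti > 0, "ti must be a positive scalar")
  1 - 2 * exp(-ti / t1)
}
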
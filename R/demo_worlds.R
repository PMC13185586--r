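#' Bundled calibration worlds
#'
#' Three small, fully specified synthetic "worlds" used by the package's
#' calibration suite and demo runs. Their parameters are part of the
#' package's stated conditions (see the methods vignette) and are not
#' meant to be tuned.
#'
#' `demo_exposure_world()`: a 3000-nt segment whose background
#' accessibility varies sinusoidally along the genome (temperature-flat,
#' 100-nt strips, exposure 0.35-0.55) with two planted 100-nt logistic
#' barrier regions at T50 = 55 and 65 degrees C (k = 6, amplitude 0.5).
#' The gradient keeps background coverage shares flat across the
#' temperature series while giving the priming track continuous rank
#' structure.
#'
#' `demo_crosslink_world()`: a 500-nt segment carrying exactly 50 U
#' positions (every 9 nt from 32 to 473), of which 20 are crosslink
#' sites at `p_xl = 0.4` over a background transition rate of 0.01, read
#' at uniform exposure 0.3.
#'
#' `demo_anticorrelation_world()`: a 2000-nt segment with a single
#' highly exposed half (positions 500-1500 at exposure 0.5, elsewhere
#' 0.05) and 100 crosslink sites placed either exclusively outside the
#' exposed region (`placement = "outside"`) or uniformly at random
#' (`placement = "uniform"`).
#'
#' @param seed integer seed used to synthesise the reference (and to
#'   place crosslink sites where applicable).
#' @return a list with components `ref`, `barrier`, `params` and
#'   world-specific extras (see Details).
#' @name demo_worlds
NULL

#' @rdname demo_worlds
#' @export
demo_exposure_world <- function(seed = 77L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ref <- random_genome(c(RNA1 = 3000L))
  strips <- data.frame(segment = "RNA1",
                       start = seq(1L, 2901L, by = 100L),
                       end = seq(100L, 3000L, by = 100L),
                       b = 0.45 + 0.10 * sin(2 * pi * (0:29) / 15),
                       a = 0, t50 = 60, k = 2)
  planted <- data.frame(segment = "RNA1", start = c(801L, 2001L),
                        end = c(900L, 2100L),
                        b = 0.45, a = 0.5, t50 = c(55, 65), k = 6)
  list(ref = ref,
       barrier = barrier_model(rbind(strips, planted), default_exposure = 0.05),
       params = library_params(n_fragments = 100000L),
       planted_regions = c("RNA1:801-900", "RNA1:2001-2100"),
       background_regions = c("RNA1:1101-1200", "RNA1:2601-2700"))
}

#' @rdname demo_worlds
#' @export
demo_crosslink_world <- function(seed = 123L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  u_pos <- seq(32L, 473L, by = 9L)  # 50 U positions
  chars <- sample(c("A", "C", "G"), 500L, replace = TRUE)
  chars[u_pos] <- "T"
  ref <- genome_reference(c(XL = paste(chars, collapse = "")))
  planted <- u_pos[seq(1L, 39L, by = 2L)]  # 20 crosslink sites
  profile <- structure(list(XL = rep(0.3, 500L)), class = "exposure_profile",
                       temperature = 50)
  list(ref = ref,
       profile = profile,
       params = library_params(n_fragments = 48000L),
       u_positions = u_pos,
       planted_sites = planted,
       xl = crosslink_profile(ref, data.frame(segment = "XL", pos = planted,
                                              p_xl = 0.4), p_bg = 0.01),
       xl_null = crosslink_profile(ref, NULL, p_bg = 0.01),
       min_depth = 1000L)
}

#' @rdname demo_worlds
#' @param placement `"outside"` (crosslink sites only outside the
#'   exposed region) or `"uniform"`.
#' @export
demo_anticorrelation_world <- function(seed = 55L, placement = c("outside", "uniform")) {
  placement <- match.arg(placement)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ref <- random_genome(c(S = 2000L))
  tp <- t_positions(ref, "S")
  barrier <- barrier_model(data.frame(segment = "S", start = 500L, end = 1500L,
                                      b = 0.5, a = 0, t50 = 60, k = 2),
                           default_exposure = 0.05)
  pool <- if (placement == "outside") tp[tp < 494L | tp > 1506L] else tp
  sites <- sample(pool, 100L)
  list(ref = ref,
       barrier = barrier,
       params = library_params(n_fragments = 60000L),
       sites = sites,
       xl = crosslink_profile(ref, data.frame(segment = "S", pos = sites,
                                              p_xl = 0.3), p_bg = 0.01),
       min_depth = 100L)
}
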
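#' Synthetic dataset configuration
#'
#' Describes a generated benchmark of fixed-length windows with a uridine
#' at the centre. Negatives are drawn i.i.d. from the background
#' composition (centre forced to U); positives additionally carry a planted
#' position weight matrix (PWM) signal in the flank around the centre,
#' mixed with the background at weight \code{motif_strength}. The planted
#' motif loosely mimics a tRNA T-loop-like context (G-rich upstream,
#' UC-rich downstream of the modified U) so that positional, compositional
#' and pair-based encoders can all pick up part of the signal.
#'
#' @param n_pos,n_neg numbers of positive and negative windows.
#' @param L odd window length, default 41.
#' @param motif_strength mixture weight of the PWM in [0, 1]; 0 makes the
#'   classes exchangeable.
#' @param motif_halfwidth the PWM covers centre +/- this many positions
#'   (must be < (L-1)/2).
#' @param background length-4 nucleotide probability vector (A, C, G, U).
#' @param group_tags optional named list, e.g.
#'   \code{list(technique = c("miCLIP", "FICC"))}; values are assigned
#'   round-robin within each class.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class \code{m5u_synth_config}.
#' @export
synth_config <- function(n_pos = 200L, n_neg = 200L, L = 41L,
                         motif_strength = 0.8, motif_halfwidth = 5L,
                         background = rep(0.25, 4), group_tags = NULL,
                         seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, L %% 2L == 1L,
            motif_strength >= 0, motif_strength <= 1,
            motif_halfwidth >= 1L, motif_halfwidth < (L - 1L) %/% 2L)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 probabilities summing to 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = as.integer(L), motif_strength = motif_strength,
                 motif_halfwidth = as.integer(motif_halfwidth),
                 background = as.numeric(background),
                 group_tags = group_tags, seed = as.integer(seed)),
            class = "m5u_synth_config")
}

#' The fixed planted motif PWM
#'
#' Rows are flank positions centre-hw .. centre+hw (the centre row is a
#' point mass on U, as every window has U there); columns are A, C, G, U.
#' Upstream favours G, the immediate downstream favours U then C then G
#' then A, echoing the GU(U)CGA-like context of tRNA T-loop m5U sites.
#'
#' @param motif_halfwidth flank half-width.
#' @return a (2*hw+1) x 4 matrix with rows summing to 1.
#' @export
synth_pwm <- function(motif_halfwidth = 5L) {
  hw <- motif_halfwidth
  peak <- function(nt, p = 0.7) {
    v <- rep((1 - p) / 3, 4)
    v[match(nt, M5U_ALPHABET)] <- p
    v
  }
  up <- c("G", "G", "C", "G", "G")     # ... five positions upstream
  down <- c("U", "C", "G", "A", "U")   # five downstream
  rows <- lapply(seq_len(2L * hw + 1L), function(r) {
    off <- r - hw - 1L                 # offset from centre
    if (off == 0L) return(c(0, 0, 0, 1))
    if (off < 0L) peak(up[((-off - 1L) %% 5L) + 1L])
    else peak(down[((off - 1L) %% 5L) + 1L])
  })
  pwm <- do.call(rbind, rows)
  dimnames(pwm) <- list(sprintf("%+d", (-hw):hw), M5U_ALPHABET)
  pwm
}

#' Generate a synthetic labeled window dataset
#'
#' @param cfg an \code{\link{synth_config}}.
#' @return an \code{m5u_dataset} (positives first, then negatives, each in
#'   generation order).
#' @export
generate_windows <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "m5u_synth_config"))
  L <- cfg$L
  hw <- cfg$motif_halfwidth
  center <- (L + 1L) %/% 2L
  pwm <- synth_pwm(hw)
  withr::with_seed(cfg$seed, {
    draw <- function(n, probs_by_pos) {
      vapply(seq_len(n), function(i) {
        nts <- vapply(seq_len(L), function(p) {
          sample(M5U_ALPHABET, 1L, prob = probs_by_pos[[p]])
        }, character(1L))
        nts[center] <- "U"
        paste(nts, collapse = "")
      }, character(1L))
    }
    bg <- lapply(seq_len(L), function(p) cfg$background)
    pos_probs <- bg
    for (r in seq_len(2L * hw + 1L)) {
      p <- center - hw - 1L + r
      pos_probs[[p]] <- cfg$motif_strength * pwm[r, ] +
        (1 - cfg$motif_strength) * cfg$background
    }
    pos_probs[[center]] <- c(0, 0, 0, 1)
    seqs <- c(draw(cfg$n_pos, pos_probs), draw(cfg$n_neg, bg))
  })
  id <- c(sprintf("pos_%04d", seq_len(cfg$n_pos)),
          sprintf("neg_%04d", seq_len(cfg$n_neg)))
  label <- rep(c("positive", "negative"), c(cfg$n_pos, cfg$n_neg))
  groups <- NULL
  if (!is.null(cfg$group_tags)) {
    groups <- as.data.frame(lapply(cfg$group_tags, function(vals) {
      c(rep_len(vals, cfg$n_pos), rep_len(vals, cfg$n_neg))
    }), stringsAsFactors = FALSE)
  }
  m5u_dataset(id, seqs, label, groups = groups, L = L)
}

#' Generation manifest
#'
#' A JSON-serializable record of every generator parameter, the PWM and the
#' seed, sufficient to regenerate the dataset exactly.
#'
#' @param cfg an \code{\link{synth_config}}.
#' @return a named list.
#' @export
describe_synth <- function(cfg = synth_config()) {
  pwm <- synth_pwm(cfg$motif_halfwidth)
  list(generator = "m5ugraph::generate_windows",
       n_pos = cfg$n_pos, n_neg = cfg$n_neg, L = cfg$L,
       motif_strength = cfg$motif_strength,
       motif_halfwidth = cfg$motif_halfwidth,
       background = cfg$background,
       group_tags = cfg$group_tags,
       seed = cfg$seed,
       pwm = list(positions = rownames(pwm),
                  alphabet = colnames(pwm),
                  probs = unname(apply(pwm, 1L, function(r) r, simplify = FALSE))))
}

#' Write a synthetic dataset to a directory
#'
#' Emits \code{windows.fasta}, \code{labels.tsv} and \code{manifest.json}.
#'
#' @param cfg an \code{\link{synth_config}}.
#' @param dir output directory (created if missing).
#' @return the generated \code{m5u_dataset}, invisibly.
#' @export
write_synth <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_windows(cfg)
  write_windows(ds, file.path(dir, "windows.fasta"),
                file.path(dir, "labels.tsv"))
  jsonlite::write_json(describe_synth(cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}
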
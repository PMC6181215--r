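#' Pairwise recombination fraction between two RIL markers
#'
#' The observed fraction `R` of lines whose calls differ (computed over
#' lines where both markers are informative; `U` is treated as missing) is
#' converted to the per-meiosis recombination fraction for selfed RILs via
#' `r = R / (2 - 2R)` and clamped to `[0, 0.5)`.
#'
#' @param x,y character (`A`/`B`/`U`) or numeric (`-1`/`+1`/`NA`) marker
#'   vectors over the same lines.
#' @param min_informative fewer informative line pairs than this flags the
#'   estimate unreliable (default 10).
#' @return list `(r, R, n, reliable)`.
#' @export
rf_pair <- function(x, y, min_informative = 10) {
  x <- marker_to_num(x); y <- marker_to_num(y)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L) return(list(r = NA_real_, R = NA_real_, n = 0L, reliable = FALSE))
  R <- mean(x[ok] != y[ok])
  list(r = ril_selfing_r(R), R = R, n = n, reliable = n >= min_informative)
}

#' Adjacent-pair recombination fractions for a marker matrix
#'
#' @param markers lines x markers matrix in `{A, B, U}` (or `-1/+1/NA`),
#'   columns in map order within one chromosome.
#' @param min_informative see [rf_pair()].
#' @return data.frame with one row per adjacent pair: `(left, right, r, R,
#'   n, reliable)`.
#' @export
estimate_rf <- function(markers, min_informative = 10) {
  m <- ncol(markers)
  if (m < 2L) stop("need at least two markers", call. = FALSE)
  out <- lapply(seq_len(m - 1L), function(j) {
    p <- rf_pair(markers[, j], markers[, j + 1L], min_informative)
    data.frame(left = colnames(markers)[j], right = colnames(markers)[j + 1L],
               r = p$r, R = p$R, n = p$n, reliable = p$reliable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

marker_to_num <- function(x) {
  if (is.character(x)) {
    out <- rep(NA_real_, length(x))
    out[x == "A"] <- -1
    out[x == "B"] <- 1
    out
  } else as.numeric(x)
}

#' Build a genetic linkage map from bin markers
#'
#' Markers are taken in physical order (the reference genome is known for
#' this design), adjacent recombination fractions are estimated with
#' [estimate_rf()], converted to cM with the chosen mapping function and
#' accumulated per chromosome.
#'
#' @param markers lines x markers matrix in `{A, B, U}`.
#' @param positions data.frame `(chrom, pos, marker)` matching the marker
#'   columns (as from [bin_to_markers()]).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param min_informative see [rf_pair()].
#' @param reorder sort markers by physical position within chromosome
#'   (default); set `FALSE` to keep the column order as given (used by
#'   [ripple_check()] after reordering).
#' @return object of class `linkage_map`: a list whose `table` element is a
#'   data.frame `(chrom, marker, pos, cm, rf_to_next)`.
#' @export
build_linkage_map <- function(markers, positions,
                              mapping_function = c("kosambi", "haldane"),
                              min_informative = 10, reorder = TRUE) {
  mapping_function <- match.arg(mapping_function)
  stopifnot(ncol(markers) == nrow(positions))
  mf <- map_function(mapping_function)
  rows <- list()
  for (cc in unique(positions$chrom)) {
    idx <- which(positions$chrom == cc)
    if (reorder) idx <- idx[order(positions$pos[idx])]
    cm <- 0
    rf_next <- rep(NA_real_, length(idx))
    cms <- numeric(length(idx))
    for (j in seq_along(idx)) {
      cms[j] <- cm
      if (j < length(idx)) {
        p <- rf_pair(markers[, idx[j]], markers[, idx[j + 1L]],
                     min_informative)
        rf_next[j] <- p$r
        cm <- cm + if (is.na(p$r)) 0 else mf$to_cm(p$r)
      }
    }
    rows[[cc]] <- data.frame(chrom = cc,
                             marker = positions$marker[idx],
                             pos = positions$pos[idx],
                             cm = cms, rf_to_next = rf_next,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, mapping_function = mapping_function),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  len <- tapply(x$table$cm, x$table$chrom, max)
  cat("Linkage map:", nrow(x$table), "markers on", length(len),
      "chromosome(s), total", round(sum(len), 1), "cM (",
      x$mapping_function, ")\n")
  invisible(x)
}

## sum of adjacent recombination fractions for one marker order
sarf <- function(rfmat, ord) {
  sum(rfmat[cbind(ord[-length(ord)], ord[-1L])])
}

#' Verify marker order by sum-of-adjacent-recombination-fraction ripple
#'
#' For each sliding window of `window` markers, all within-window
#' permutations are scored by the sum of adjacent recombination fractions
#' (SARF) of the whole chromosome order; a permutation that strictly lowers
#' the SARF is applied.  Passes repeat until a full pass makes no change.
#' With markers initialized in physical order this confirms (or locally
#' repairs) the order; SARF never increases.
#'
#' @param markers lines x markers matrix in `{A, B, U}`.
#' @param positions data.frame `(chrom, pos, marker)` giving the initial
#'   (physical) order.
#' @param window ripple window size (default 3).
#' @param mapping_function passed to [build_linkage_map()] for the
#'   re-estimated map.
#' @return list with `map` (a [build_linkage_map()] result using the
#'   verified order), `order` (marker names per chromosome), `swaps`
#'   (data.frame of applied changes) and `sarf` (per-chromosome before /
#'   after).
#' @export
ripple_check <- function(markers, positions, window = 3,
                         mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  num <- apply(markers, 2L, marker_to_num)
  swaps <- list()
  sarf_tab <- list()
  new_positions <- list()
  for (cc in unique(positions$chrom)) {
    idx <- which(positions$chrom == cc)
    idx <- idx[order(positions$pos[idx])]
    m <- length(idx)
    if (m < 2L) {
      new_positions[[cc]] <- positions[idx, , drop = FALSE]
      next
    }
    rfmat <- rf_matrix(num[, idx, drop = FALSE])
    ord <- seq_len(m)
    before <- sarf(rfmat, ord)
    if (m > 2L) {
      w <- min(window, m)
      perms <- permutations(w)
      repeat {
        changed <- FALSE
        for (s in seq_len(m - w + 1L)) {
          seg <- s:(s + w - 1L)
          best <- sarf(rfmat, ord)
          best_perm <- NULL
          for (p in seq_len(nrow(perms))) {
            cand <- ord
            cand[seg] <- ord[seg][perms[p, ]]
            sc <- sarf(rfmat, cand)
            if (sc < best - 1e-12) { best <- sc; best_perm <- cand }
          }
          if (!is.null(best_perm)) {
            swaps[[length(swaps) + 1L]] <- data.frame(
              chrom = cc, window_start = s,
              order_before = paste(positions$marker[idx][ord[seg]],
                                   collapse = ","),
              order_after = paste(positions$marker[idx][best_perm[seg]],
                                  collapse = ","),
              stringsAsFactors = FALSE)
            ord <- best_perm
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
    after <- sarf(rfmat, ord)
    sarf_tab[[cc]] <- data.frame(chrom = cc, sarf_before = before,
                                 sarf_after = after, stringsAsFactors = FALSE)
    new_positions[[cc]] <- positions[idx[ord], , drop = FALSE]
  }
  pos2 <- do.call(rbind, new_positions)
  rownames(pos2) <- NULL
  list(map = build_linkage_map(markers[, pos2$marker, drop = FALSE],
                               pos2, mapping_function, reorder = FALSE),
       order = split(pos2$marker, pos2$chrom),
       swaps = if (length(swaps)) do.call(rbind, swaps) else
         data.frame(chrom = character(), window_start = integer(),
                    order_before = character(), order_after = character(),
                    stringsAsFactors = FALSE),
       sarf = do.call(rbind, sarf_tab))
}

rf_matrix <- function(num) {
  m <- ncol(num)
  rf <- matrix(0, m, m)
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      p <- rf_pair(num[, j], num[, k])
      rf[j, k] <- rf[k, j] <- if (is.na(p$r)) 0.5 else p$r
    }
  }
  rf
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}
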
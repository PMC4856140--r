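# Half-dataset and anomalous data-quality statistics.

#' R_split between half-dataset intensities
#'
#' `R_split = 2^(-1/2) * sum|I1 - I2| / (0.5 * sum(I1 + I2))`, computed
#' over reflections present in both halves.  Invariant under global
#' rescaling; undefined (NA) when the denominator is not positive.
#'
#' @param half1,half2 Numeric vectors of half-set merged intensities for
#'   common unique reflections.
#' @return R_split value.
#' @export
r_split <- function(half1, half2) {
  ok <- is.finite(half1) & is.finite(half2)
  if (!any(ok)) return(NA_real_)
  den <- 0.5 * sum(half1[ok] + half2[ok])
  if (den <= 0) return(NA_real_)
  sum(abs(half1[ok] - half2[ok])) / sqrt(2) / den
}

#' CC1/2 and CC*
#'
#' Pearson correlation between half-dataset intensities, and the implied
#' full-data correlation to truth `CC* = sqrt(2 CC1/2 / (1 + CC1/2))`
#' (NA when CC1/2 < 0).
#'
#' @inheritParams r_split
#' @return List with `cc_half` and `cc_star`.
#' @export
cc_half_and_star <- function(half1, half2) {
  ok <- is.finite(half1) & is.finite(half2)
  if (sum(ok) < 3) return(list(cc_half = NA_real_, cc_star = NA_real_))
  if (stats::sd(half1[ok]) == 0 || stats::sd(half2[ok]) == 0)
    return(list(cc_half = NA_real_, cc_star = NA_real_))
  cc <- stats::cor(half1[ok], half2[ok])
  star <- if (cc < 0) NA_real_ else sqrt(2 * cc / (1 + cc))
  list(cc_half = cc, cc_star = star)
}

# Extract the acentric Bijvoet-pair table from an anomalous merge:
# one row per unique with both mates present.
bijvoet_pairs <- function(merged) {
  if (!isTRUE(attr(merged, "anomalous")))
    stop("anomalous merged data required")
  p <- merged[merged$sign == "+", ]
  m <- merged[merged$sign == "-", ]
  kp <- encode_hkl(as.matrix(p[, c("h", "k", "l")]))
  km <- encode_hkl(as.matrix(m[, c("h", "k", "l")]))
  i <- match(kp, km)
  ok <- !is.na(i)
  data.frame(h = p$h[ok], k = p$k[ok], l = p$l[ok], d = p$d[ok],
             I_plus = p$I[ok], I_minus = m$I[i[ok]],
             Ip1 = p$I1[ok], Ip2 = p$I2[ok],
             Im1 = m$I1[i[ok]], Im2 = m$I2[i[ok]],
             np1 = p$n1[ok], np2 = p$n2[ok],
             nm1 = m$n1[i[ok]], nm2 = m$n2[i[ok]])
}

#' Anomalous difference statistics
#'
#' `R_ano = sum|I+ - I-| / (0.5 * sum(I+ + I-))` over acentric
#' reflections with both Bijvoet mates observed, and `CC_ano`, the
#' Pearson correlation of the Bijvoet difference `dI = I+ - I-` between
#' the two image half-sets (reproducibility of the anomalous signal).
#'
#' @param merged An anomalous `sfx_merged`.
#' @return List with `r_ano`, `cc_ano`, `n_pairs`.
#' @export
anomalous_stats <- function(merged) {
  bp <- bijvoet_pairs(merged)
  if (nrow(bp) == 0) stop("no complete Bijvoet pairs")
  den <- 0.5 * sum(bp$I_plus + bp$I_minus)
  r_ano <- if (den > 0) sum(abs(bp$I_plus - bp$I_minus)) / den else NA_real_
  ok <- bp$np1 > 0 & bp$np2 > 0 & bp$nm1 > 0 & bp$nm2 > 0
  cc_ano <- if (sum(ok) >= 3) {
    d1 <- bp$Ip1[ok] - bp$Im1[ok]
    d2 <- bp$Ip2[ok] - bp$Im2[ok]
    if (stats::sd(d1) > 0 && stats::sd(d2) > 0) stats::cor(d1, d2)
    else NA_real_
  } else NA_real_
  list(r_ano = r_ano, cc_ano = cc_ano, n_pairs = nrow(bp))
}

#' Resolution-shelled quality statistics
#'
#' Bins unique reflections into resolution shells (equal unique counts by
#' default) and tabulates completeness, multiplicity, SNR, R_split,
#' CC1/2, CC*, R_ano, CC_ano and R_ano/R_split per shell plus a pooled
#' overall row.  Completeness counts distinct asymmetric-unit reflections
#' (Bijvoet mates separately when the merge is anomalous) against the
#' theoretically possible set for the space group in the shell.
#' Reflections present in only one half are excluded from the paired
#' metrics but counted in completeness and SNR; undefined metrics are NA.
#'
#' @param merged An `sfx_merged`.
#' @param n_shells Number of shells.
#' @param d_range Optional c(d_max, d_min) restriction in Angstrom.
#' @return Data frame of class `sfx_shell_table`; the last row (shell NA,
#'   labelled "overall") pools all reflections.
#' @export
shell_stats <- function(merged, n_shells = 10, d_range = NULL) {
  cell <- attr(merged, "cell"); sg <- attr(merged, "sg")
  anomalous <- isTRUE(attr(merged, "anomalous"))
  x <- as.data.frame(merged)
  if (!is.null(d_range))
    x <- x[x$d <= max(d_range) & x$d >= min(d_range), ]
  dmin <- min(x$d); dmax <- max(x$d)
  # theoretical unique set, anomalous-aware
  theo <- reflection_table(cell, sg, d_min = dmin, d_max = dmax)
  theo_n <- if (anomalous) nrow(theo) + sum(!theo$centric) else nrow(theo)
  # shells with equal counts of observed base uniques
  base <- x[!duplicated(x[, c("h", "k", "l")]), c("h", "k", "l", "d")]
  base <- base[order(-base$d), ]
  if (n_shells > nrow(base)) stop("n_shells exceeds unique reflection count")
  edges_idx <- round(seq(0, nrow(base), length.out = n_shells + 1))
  inner <- edges_idx[2:n_shells]           # last base index of shells 1..n-1
  mids <- (base$d[inner] + base$d[pmin(inner + 1, nrow(base))]) / 2
  shell_of <- function(d) {
    if (n_shells == 1) return(rep(1L, length(d)))
    findInterval(-d, -mids) + 1L
  }
  x$shell <- shell_of(x$d)
  theo$shell <- shell_of(theo$d)
  theo$nclass <- if (anomalous) ifelse(theo$centric, 1L, 2L) else 1L

  one_shell <- function(xs, n_theo) {
    if (nrow(xs) == 0)
      return(data.frame(d_max = NA_real_, d_min = NA_real_, n_unique = 0L,
                        completeness = 0, multiplicity = NA_real_,
                        snr = NA_real_, r_split = NA_real_,
                        cc_half = NA_real_, cc_star = NA_real_,
                        r_ano = NA_real_, cc_ano = NA_real_,
                        ratio_ano_split = NA_real_))
    hs <- xs$n1 > 0 & xs$n2 > 0
    rs <- r_split(xs$I1[hs], xs$I2[hs])
    cc <- cc_half_and_star(xs$I1[hs], xs$I2[hs])
    an <- list(r_ano = NA_real_, cc_ano = NA_real_)
    if (anomalous && any(xs$sign != "0")) {
      aa <- attributes(merged)
      xs2 <- structure(xs, cell = aa$cell, sg = aa$sg, anomalous = TRUE,
                       class = c("sfx_merged", "data.frame"))
      an <- tryCatch(anomalous_stats(xs2),
                     error = function(e) an)
    }
    data.frame(d_max = max(xs$d), d_min = min(xs$d),
               n_unique = nrow(xs),
               completeness = 100 * nrow(xs) / n_theo,
               multiplicity = mean(xs$mult),
               snr = mean(xs$I / xs$sigma),
               r_split = rs, cc_half = cc$cc_half, cc_star = cc$cc_star,
               r_ano = an$r_ano, cc_ano = an$cc_ano,
               ratio_ano_split = if (is.na(rs) || is.na(an$r_ano))
                 NA_real_ else an$r_ano / rs)
  }
  rows <- lapply(seq_len(n_shells), function(s)
    one_shell(x[x$shell == s, ], sum(theo$nclass[theo$shell == s])))
  overall <- one_shell(x, theo_n)
  out <- cbind(shell = c(as.character(seq_len(n_shells)), "overall"),
               rbind(do.call(rbind, rows), overall))
  class(out) <- c("sfx_shell_table", class(out))
  out
}

#' @export
print.sfx_shell_table <- function(x, digits = 3, ...) {
  cat("resolution-shelled data quality\n")
  print.data.frame(format(as.data.frame(x), digits = digits, nsmall = 0),
                   row.names = FALSE)
  invisible(x)
}

#' Write a shell table as CSV
#'
#' @param x An `sfx_shell_table`.
#' @param path Output file.
#' @export
write_shell_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
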
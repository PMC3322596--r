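#' Histogram of interatomic-distance differences
#'
#' Pools the \eqn{\Delta} values of all supplied restraint lists (all chain
#' pairs) into fixed-width bins starting at zero; the final bin is open and
#' collects any overflow. The first bin is `[0, bin_width)`.
#'
#' @param lists a `restraint_list` or list of them.
#' @param s the structure (current coordinates).
#' @param bin_width bin width in Angstrom, default 0.1.
#' @param target fixed target structure for target-kind lists.
#' @return a `delta_histogram`: list with `breaks`, `counts`, `total`,
#'   `bin_width`.
#' @export
delta_histogram <- function(lists, s, bin_width = 0.1, target = NULL) {
  if (inherits(lists, "restraint_list")) lists <- list(lists)
  lists <- lapply(lists, evaluate_restraints, s = s, target = target)
  deltas <- unlist(lapply(lists, function(rl) rl$restraints$delta))
  if (!length(deltas)) stop("no restraints supplied to delta_histogram")
  nb <- max(1L, ceiling(max(deltas) / bin_width + 1e-9))
  breaks <- seq(0, nb * bin_width, by = bin_width)
  idx <- pmin(floor(deltas / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(breaks = breaks, counts = counts,
                 total = length(deltas), bin_width = bin_width),
            class = "delta_histogram")
}

#' @export
print.delta_histogram <- function(x, ...) {
  cat(sprintf("<delta_histogram: %d values, %d bins of %.2f A; first bin %.1f%%>\n",
              x$total, length(x$counts), x$bin_width,
              100 * x$counts[1] / x$total))
  invisible(x)
}

#' Write a delta histogram as TSV
#'
#' @param h a `delta_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  utils::write.table(
    data.frame(bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
               count = h$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-atom contact comparison across NCS copies
#'
#' For one focus atom, lists every restrained partner with the distance in
#' each copy and the difference — the per-atom table used to inspect how
#' similar the environments of NCS-equivalent atoms are. Distances are
#' reported to 3 decimal places; the difference is computed on unrounded
#' distances and then rounded to 2 decimal places.
#'
#' @param s a `lssr_structure`.
#' @param chain_pair length-2 character vector; the focus atom lives in the
#'   first chain.
#' @param focus list with `resnum`, `atom` and optionally `icode`.
#' @param params [lssr_params()] (the cutoff controls which partners appear).
#' @return data frame: `atom_j`, `r1`, `atom_jp`, `r2`, `delta` — one row
#'   per restrained partner of the focus atom.
#' @export
contact_report <- function(s, chain_pair, focus, params = lssr_params()) {
  stopifnot(length(chain_pair) == 2)
  icode <- if (is.null(focus$icode)) "" else focus$icode
  a <- s$atoms
  f_row <- which(a$chain == chain_pair[1] & a$resnum == focus$resnum &
                   a$icode == icode & a$atom == focus$atom)
  if (!length(f_row)) {
    stop(sprintf("focus atom %s%d %s not found in chain %s",
                 chain_pair[1], focus$resnum, focus$atom, chain_pair[1]))
  }
  corr <- match_atoms(s, chain_pair[1], chain_pair[2])
  if (!f_row %in% corr$idx_a) {
    stop(sprintf("focus atom %s%d %s has no equivalent in chain %s",
                 chain_pair[1], focus$resnum, focus$atom, chain_pair[2]))
  }
  rl <- enumerate_restraints(s, corr, params = params)
  r <- rl$restraints
  hit <- r$i1 == f_row | r$j1 == f_row
  r <- r[hit, , drop = FALSE]
  partner1 <- ifelse(r$i1 == f_row, r$j1, r$i1)
  partner2 <- ifelse(r$i1 == f_row, r$j2, r$i2)
  lab <- function(rows) {
    paste0(a$chain[rows], a$resnum[rows], a$icode[rows], " ", a$atom[rows])
  }
  out <- data.frame(
    atom_j = lab(partner1),
    r1 = round(r$r1, 3),
    atom_jp = lab(partner2),
    r2 = round(r$r2, 3),
    delta = round(abs(r$r1 - r$r2), 2),
    stringsAsFactors = FALSE
  )
  out <- out[order(a$resnum[partner1], a$atom[partner1]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
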
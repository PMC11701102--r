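#' Read a gel band-intensity table
#'
#' TSV/CSV with columns `protein`, `replicate`, `intensity`, `mw_kda`
#' (densitometry units and kilodaltons).
#'
#' @param path File path; `.csv` is comma-separated, otherwise tab.
#' @return data.frame of band measurements.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read band table: '", path, "' does not exist", call. = FALSE)
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("protein", "replicate", "intensity", "mw_kda"),
                     names(tab))
  if (length(missing)) {
    stop("band table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$intensity < 0)) stop("negative band intensity", call. = FALSE)
  if (any(tab$mw_kda <= 0)) stop("molecular weights must be positive", call. = FALSE)
  tab
}

#' Molar ratios from gel densitometry
#'
#' Converts band intensities to molar ratios: within each replicate the
#' intensity of every protein is divided by its molecular weight (stain
#' signal scales with mass, so intensity/MW is proportional to moles) and
#' expressed relative to the reference protein. Ratios are then summarised
#' as mean and sample standard deviation (divisor n-1) across replicates,
#' the convention for small numbers of independent experiments. Molecular
#' weights should be the tagged construct masses actually on the gel, not
#' database masses.
#'
#' @param bands data.frame with columns `protein`, `replicate`,
#'   `intensity`, `mw_kda` (see [read_band_table()]).
#' @param reference Name of the reference protein (ratio 1 by
#'   construction); must be present with positive intensity in every
#'   replicate.
#' @return Object of class `molar_ratio_report`: data.frame `table` with
#'   `protein`, `ratio_mean`, `ratio_sd`, `n`, plus `per_replicate`.
#' @examples
#' gel <- make_gel(seed = 2)
#' molar_ratios(gel$bands, reference = "Spc97")
#' @export
molar_ratios <- function(bands, reference) {
  stopifnot(is.data.frame(bands),
            all(c("protein", "replicate", "intensity", "mw_kda") %in%
                  names(bands)))
  reps <- sort(unique(bands$replicate))
  per <- lapply(reps, function(rep) {
    sub <- bands[bands$replicate == rep, , drop = FALSE]
    ref <- sub[sub$protein == reference, , drop = FALSE]
    if (nrow(ref) == 0L || ref$intensity[1] <= 0) {
      stop("reference protein '", reference,
           "' missing or has zero intensity in replicate ", rep,
           call. = FALSE)
    }
    mol <- sub$intensity / sub$mw_kda
    ref_mol <- ref$intensity[1] / ref$mw_kda[1]
    data.frame(replicate = rep, protein = sub$protein,
               ratio = mol / ref_mol, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  prots <- unique(bands$protein)
  tab <- do.call(rbind, lapply(prots, function(p) {
    r <- per$ratio[per$protein == p]
    data.frame(protein = p, ratio_mean = mean(r),
               ratio_sd = if (length(r) > 1) stats::sd(r) else 0,
               n = length(r), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, per_replicate = per, reference = reference),
            class = "molar_ratio_report")
}

#' @export
print.molar_ratio_report <- function(x, ...) {
  cat("molar ratios relative to", x$reference,
      sprintf("(mean +/- sample SD, N = %d replicates)\n",
              max(x$table$n)))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-14s %5.2f +/- %.2f\n", t$protein[i],
                t$ratio_mean[i], t$ratio_sd[i]))
  }
  invisible(x)
}
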
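#' Back-exchange corrected deuterium uptake fraction
#'
#' Uptake of a peptide relative to its undeuterated (`m0`) and fully
#' deuterated (`m100`) controls: `(m_t - m0) / (m100 - m0)`. Normalising
#' by the 100%-deuterated control corrects for back-exchange during
#' workup. Values are clamped to [0, 1]; the raw (unclamped) values are
#' attached as attribute `"raw"` so measurement noise outside the range
#' remains inspectable.
#'
#' @param m_t Centroid mass after labelling (Da); vectorised.
#' @param m0 Centroid mass of the undeuterated control (Da).
#' @param m100 Centroid mass of the 100%-deuterated control (Da).
#' @return Numeric vector of uptake fractions in [0, 1].
#' @examples
#' uptake_fraction(1005, 1000, 1010)  # 0.5
#' @export
uptake_fraction <- function(m_t, m0, m100) {
  if (any(m100 <= m0)) {
    stop("invalid controls: m100 must exceed m0 for every peptide",
         call. = FALSE)
  }
  raw <- (m_t - m0) / (m100 - m0)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

hx_required_cols <- c("peptide_id", "start", "end", "m0", "m_t", "m100")

#' Read a peptide-exchange table
#'
#' Reads a TSV/CSV of peptide centroid masses. Required columns:
#' `peptide_id`, `start`, `end`, `m0`, `m_t`, `m100`; optional:
#' `sequence`, `condition`, `charge`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` is comma, otherwise tab).
#' @return data.frame of peptide-exchange rows.
#' @export
read_hx_table <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read exchange table: '", path, "' does not exist",
         call. = FALSE)
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(hx_required_cols, names(tab))
  if (length(missing)) {
    stop("exchange table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

# average centroid masses over charge states, one row per peptide
collapse_charge_states <- function(tab) {
  key <- paste(tab$start, tab$end,
               if ("sequence" %in% names(tab)) tab$sequence else "", sep = "|")
  sp <- split(seq_len(nrow(tab)), key)
  rows <- lapply(sp, function(ix) {
    first <- tab[ix[1], , drop = FALSE]
    first$m0 <- mean(tab$m0[ix])
    first$m_t <- mean(tab$m_t[ix])
    first$m100 <- mean(tab$m100[ix])
    first
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Relative exchange and protection per peptide
#'
#' Matches peptides between a baseline (no ligand) and a ligand condition
#' by (start, end, sequence), computes back-exchange corrected exchange
#' percentages for both, and scores ligand-induced protection relative to
#' the fraction that was exchanging at baseline:
#' `relative_exchange = 100 * ligand / baseline` and
#' `relative_protection = 100 * (baseline - ligand) / baseline`, so full
#' protection by the ligand gives 100% and unchanged exchange gives 0%.
#' Peptides observed in several charge states are averaged (unweighted
#' mean of centroid masses per condition) before scoring. Peptides whose
#' baseline exchange is below 10% are flagged `shown = FALSE` — the
#' relative statistics are unstable when almost nothing exchanges in the
#' baseline — but never deleted.
#'
#' @param baseline,ligand data.frames of peptide-exchange rows (see
#'   [read_hx_table()] for columns).
#' @param baseline_min Baseline-exchange display threshold in percent,
#'   inclusive (default 10).
#' @return Object of class `protection_table`: data.frame with columns
#'   `peptide_id`, `start`, `end`, `baseline_exchange`, `ligand_exchange`,
#'   `relative_exchange`, `relative_protection`, `shown`; unmatched
#'   peptides are listed in attribute `"unmatched"`.
#' @examples
#' b <- data.frame(peptide_id = "p1", start = 5, end = 12,
#'                 m0 = 1000, m_t = 1004, m100 = 1010)
#' l <- transform(b, m_t = 1003)
#' protection_table(b, l)
#' @export
protection_table <- function(baseline, ligand, baseline_min = 10) {
  for (tab in list(baseline, ligand)) {
    missing <- setdiff(hx_required_cols, names(tab))
    if (length(missing)) {
      stop("exchange table lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  b <- collapse_charge_states(baseline)
  l <- collapse_charge_states(ligand)
  keyf <- function(tab) paste(tab$start, tab$end,
                              if ("sequence" %in% names(tab)) tab$sequence else "",
                              sep = "|")
  kb <- keyf(b); kl <- keyf(l)
  common <- intersect(kb, kl)
  if (length(common) == 0L) {
    stop("no peptides matched between baseline and ligand conditions",
         call. = FALSE)
  }
  ib <- match(common, kb); il <- match(common, kl)
  be <- 100 * as.numeric(uptake_fraction(b$m_t[ib], b$m0[ib], b$m100[ib]))
  le <- 100 * as.numeric(uptake_fraction(l$m_t[il], l$m0[il], l$m100[il]))
  rel_ex <- ifelse(be > 0, 100 * le / be, NA_real_)
  rel_prot <- ifelse(be > 0, 100 * (be - le) / be, NA_real_)
  out <- data.frame(peptide_id = b$peptide_id[ib],
                    start = b$start[ib], end = b$end[ib],
                    baseline_exchange = be, ligand_exchange = le,
                    relative_exchange = rel_ex,
                    relative_protection = rel_prot,
                    shown = be >= baseline_min,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- list(
    baseline = b$peptide_id[setdiff(seq_len(nrow(b)), ib)],
    ligand = l$peptide_id[setdiff(seq_len(nrow(l)), il)])
  attr(out, "baseline_min") <- baseline_min
  class(out) <- c("protection_table", "data.frame")
  out
}

#' Re-apply the baseline-exchange display filter
#'
#' Sets `shown = (baseline_exchange >= threshold)` on an existing
#' protection table. The threshold is inclusive ("a minimum of 10%" reads
#' as >= 10), records are only flagged, never removed, and the operation
#' is idempotent.
#'
#' @param records A `protection_table`.
#' @param threshold Percent baseline exchange (default 10).
#' @return The table with its `shown` column updated.
#' @export
apply_baseline_filter <- function(records, threshold = 10) {
  stopifnot(is.data.frame(records), "baseline_exchange" %in% names(records))
  records$shown <- records$baseline_exchange >= threshold
  attr(records, "baseline_min") <- threshold
  records
}

#' Consolidate peptide-level protection to residues
#'
#' For each residue, averages `relative_exchange` over all shown peptides
#' covering it (inclusive start..end spans); residues covered by no shown
#' peptide are `NA`. The result can be painted onto a structure via
#' [set_bfactor()] and [write_structure()] for visual inspection of
#' protected epitopes.
#'
#' @param records A `protection_table`.
#' @param length Protein length (number of residues).
#' @param value Column to consolidate (default `"relative_exchange"`).
#' @return data.frame with `residue`, `value`, `n_peptides`, `covered`.
#' @examples
#' b <- data.frame(peptide_id = c("p1", "p2"), start = c(5, 7),
#'                 end = c(8, 10), m0 = 1000,
#'                 m_t = c(1004, 1004), m100 = 1010)
#' l <- transform(b, m_t = c(1002.4, 1001.8))
#' residue_consolidation(protection_table(b, l), length = 12)
#' @export
residue_consolidation <- function(records, length,
                                  value = "relative_exchange") {
  stopifnot(is.data.frame(records), value %in% names(records))
  shown <- records[records$shown & !is.na(records[[value]]), , drop = FALSE]
  if (nrow(shown) == 0L) {
    stop("no shown peptides to consolidate", call. = FALSE)
  }
  sums <- numeric(length)
  counts <- integer(length)
  for (i in seq_len(nrow(shown))) {
    span <- shown$start[i]:shown$end[i]
    span <- span[span >= 1 & span <= length]
    sums[span] <- sums[span] + shown[[value]][i]
    counts[span] <- counts[span] + 1L
  }
  val <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  data.frame(residue = seq_len(length), value = val,
             n_peptides = counts, covered = counts > 0L)
}
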
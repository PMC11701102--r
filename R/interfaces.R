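#' Distance criteria for contact classification
#'
#' Deposited cryo-EM models carry no hydrogens, so all criteria are
#' heavy-atom distance cutoffs: donor/acceptor N/O pairs within
#' `hbond_max` count as hydrogen bonds, side-chain N of Lys/Arg (and
#' optionally His) against side-chain carboxylate O of Asp/Glu within
#' `salt_bridge_max` as salt bridges, and carbon-carbon pairs between
#' apolar side chains within `hydrophobic_max` as hydrophobic packing.
#'
#' @param hbond_max Hydrogen-bond N/O distance cutoff, Angstrom (3.5).
#' @param salt_bridge_max Salt-bridge cutoff, Angstrom (4.0).
#' @param hydrophobic_max Hydrophobic C-C cutoff, Angstrom (4.5).
#' @param his_salt_bridge Count histidine side-chain N as a salt-bridge
#'   donor (default `TRUE`).
#' @return Object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_max = 3.5, salt_bridge_max = 4.0,
                             hydrophobic_max = 4.5, his_salt_bridge = TRUE) {
  stopifnot(hbond_max > 0, salt_bridge_max > 0, hydrophobic_max > 0)
  structure(list(hbond_max = hbond_max, salt_bridge_max = salt_bridge_max,
                 hydrophobic_max = hydrophobic_max,
                 his_salt_bridge = his_salt_bridge),
            class = "contact_criteria")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# per-atom contact roles, vectorised over an atom table
atom_roles <- function(a, his_sb = TRUE) {
  el <- a$element
  nm <- a$atom
  res <- a$resname
  backbone_no <- nm %in% c("N", "O", "OXT")
  polar <- el %in% c("N", "O")
  sb_pos_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (his_sb) sb_pos_atoms$HIS <- c("ND1", "NE2")
  sb_pos <- mapply(function(r, n) n %in% (sb_pos_atoms[[r]] %||% character()),
                   res, nm, USE.NAMES = FALSE)
  sb_neg_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  sb_neg <- mapply(function(r, n) n %in% (sb_neg_atoms[[r]] %||% character()),
                   res, nm, USE.NAMES = FALSE)
  apolar_sc <- el == "C" & !(nm %in% BACKBONE_ATOMS) & res %in% APOLAR_RESIDUES
  data.frame(polar = polar, backbone_no = backbone_no,
             sb_pos = sb_pos, sb_neg = sb_neg, apolar_sc = apolar_sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find and classify inter-chain atomic contacts
#'
#' Enumerates all heavy-atom pairs between two chains within the
#' class-specific distance cutoffs and assigns each pair one label with
#' precedence salt_bridge > hydrogen bond > hydrophobic. Hydrogen bonds
#' between two backbone N/O atoms are flagged `hbond_backbone_backbone`;
#' other N/O pairs are `hbond_sidechain`. Results are ordered by
#' (residue 1, residue 2, distance) and are symmetric in the chain
#' arguments up to column swap.
#'
#' @param model A `structure_model`.
#' @param chain_a,chain_b Chain identifiers.
#' @param criteria A [contact_criteria()] object.
#' @return data.frame of class `contact_table`: columns `kind`, `chain1`,
#'   `resno1`, `resname1`, `atom1`, `chain2`, `resno2`, `resname2`,
#'   `atom2`, `distance`.
#' @export
find_contacts <- function(model, chain_a, chain_b,
                          criteria = contact_criteria()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(criteria, "contact_criteria"))
  a <- select_atoms(model, selection(chains = chain_a))
  b <- select_atoms(model, selection(chains = chain_b))
  if (nrow(a) == 0L) stop("chain '", chain_a, "' has no heavy atoms", call. = FALSE)
  if (nrow(b) == 0L) stop("chain '", chain_b, "' has no heavy atoms", call. = FALSE)
  ra <- atom_roles(a, criteria$his_salt_bridge)
  rb <- atom_roles(b, criteria$his_salt_bridge)
  maxcut <- max(criteria$hbond_max, criteria$salt_bridge_max,
                criteria$hydrophobic_max)
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  # squared distances, all pairs
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  idx <- which(d2 <= maxcut^2, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_contacts())
  i <- idx[, 1]; j <- idx[, 2]
  d <- sqrt(pmax(d2[idx], 0))
  is_sb <- ((ra$sb_pos[i] & rb$sb_neg[j]) | (ra$sb_neg[i] & rb$sb_pos[j])) &
    d <= criteria$salt_bridge_max
  is_hb <- ra$polar[i] & rb$polar[j] & d <= criteria$hbond_max
  is_hb_bb <- is_hb & ra$backbone_no[i] & rb$backbone_no[j]
  is_phob <- ra$apolar_sc[i] & rb$apolar_sc[j] & d <= criteria$hydrophobic_max
  kind <- rep(NA_character_, length(d))
  kind[is_phob] <- "hydrophobic"
  kind[is_hb] <- "hbond_sidechain"
  kind[is_hb_bb] <- "hbond_backbone_backbone"
  kind[is_sb] <- "salt_bridge"
  keep <- !is.na(kind) & d > 0
  if (!any(keep)) return(empty_contacts())
  out <- data.frame(
    kind = kind[keep],
    chain1 = a$chain[i][keep], resno1 = a$resno[i][keep],
    resname1 = a$resname[i][keep], atom1 = a$atom[i][keep],
    chain2 = b$chain[j][keep], resno2 = b$resno[j][keep],
    resname2 = b$resname[j][keep], atom2 = b$atom[j][keep],
    distance = d[keep], stringsAsFactors = FALSE
  )
  out <- out[order(out$resno1, out$resno2, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(kind = character(), chain1 = character(),
                    resno1 = integer(), resname1 = character(),
                    atom1 = character(), chain2 = character(),
                    resno2 = integer(), resname2 = character(),
                    atom2 = character(), distance = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Aggregate a contact table per residue pair
#'
#' @param contacts A `contact_table` from [find_contacts()].
#' @return data.frame with one row per (residue1, residue2, kind):
#'   number of atom pairs and minimum distance.
#' @export
contacts_by_residue <- function(contacts) {
  if (nrow(contacts) == 0L) {
    return(data.frame(chain1 = character(), resno1 = integer(),
                      resname1 = character(), chain2 = character(),
                      resno2 = integer(), resname2 = character(),
                      kind = character(), n_atom_pairs = integer(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(contacts$chain1, contacts$resno1, contacts$chain2,
               contacts$resno2, contacts$kind, sep = "|")
  sp <- split(seq_len(nrow(contacts)), key)
  rows <- lapply(sp, function(ix) {
    first <- contacts[ix[1], ]
    data.frame(chain1 = first$chain1, resno1 = first$resno1,
               resname1 = first$resname1, chain2 = first$chain2,
               resno2 = first$resno2, resname2 = first$resname2,
               kind = first$kind, n_atom_pairs = length(ix),
               min_distance = min(contacts$distance[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$resno1, out$resno2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydrophobic pocket around a probe residue
#'
#' Collects hydrophobic contacts from the side-chain carbons of one probe
#' residue (e.g. a phenylalanine docking into a neighbouring subunit) to a
#' partner chain, and reports the set of pocket residues.
#'
#' @param model A `structure_model`.
#' @param probe_chain,probe_residue Chain id and residue number of probe.
#' @param partner_chain Chain forming the pocket.
#' @param criteria A [contact_criteria()]; only `hydrophobic_max` is used.
#' @return List with `contacts` (atom-pair table: probe side-chain carbon
#'   vs partner carbon within cutoff) and `pocket` (data.frame of the
#'   partner residues, with an `apolar` flag).
#' @export
pocket_contacts <- function(model, probe_chain, probe_residue, partner_chain,
                            criteria = contact_criteria()) {
  probe <- select_atoms(model, selection(chains = probe_chain,
                                         residues = probe_residue))
  if (nrow(probe) == 0L) {
    stop("probe residue ", probe_residue, " not found in chain '",
         probe_chain, "'", call. = FALSE)
  }
  probe <- probe[probe$element == "C" & !(probe$atom %in% BACKBONE_ATOMS), ,
                 drop = FALSE]
  partner <- select_atoms(model, selection(chains = partner_chain))
  partner <- partner[partner$element == "C", , drop = FALSE]
  if (nrow(probe) == 0L || nrow(partner) == 0L) {
    return(list(contacts = empty_contacts(),
                pocket = data.frame(chain = character(), resno = integer(),
                                    resname = character(), apolar = logical(),
                                    stringsAsFactors = FALSE)))
  }
  pa <- as.matrix(probe[, c("x", "y", "z")])
  pb <- as.matrix(partner[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  idx <- which(d2 <= criteria$hydrophobic_max^2 & d2 > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(contacts = empty_contacts(),
                pocket = data.frame(chain = character(), resno = integer(),
                                    resname = character(), apolar = logical(),
                                    stringsAsFactors = FALSE)))
  }
  i <- idx[, 1]; j <- idx[, 2]
  out <- data.frame(
    kind = "hydrophobic",
    chain1 = probe$chain[i], resno1 = probe$resno[i],
    resname1 = probe$resname[i], atom1 = probe$atom[i],
    chain2 = partner$chain[j], resno2 = partner$resno[j],
    resname2 = partner$resname[j], atom2 = partner$atom[j],
    distance = sqrt(pmax(d2[idx], 0)), stringsAsFactors = FALSE
  )
  out <- out[order(out$resno1, out$resno2, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  uq <- !duplicated(paste(out$chain2, out$resno2))
  pocket <- data.frame(chain = out$chain2[uq], resno = out$resno2[uq],
                       resname = out$resname2[uq],
                       apolar = out$resname2[uq] %in% APOLAR_RESIDUES,
                       stringsAsFactors = FALSE)
  list(contacts = out, pocket = pocket)
}
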
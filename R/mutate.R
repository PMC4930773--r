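#' Parse a mutation specification string
#'
#' @param spec string of the form `"A:228:SER>PRO"`
#'   (chain:residue-number:from>to, three-letter codes).
#' @return list with `chain_id`, `seq_number`, `from_res`, `to_res`.
#' @export
parse_mutation <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+):([A-Za-z]{3})>([A-Za-z]{3})$", spec))[[1]]
  if (length(m) != 5) {
    stop("malformed mutation spec '", spec, "' (expected chain:resno:FROM>TO)")
  }
  list(
    chain_id = m[2], seq_number = as.integer(m[3]),
    from_res = toupper(m[4]), to_res = toupper(m[5])
  )
}

#' In-silico single-site point mutation
#'
#' Replaces the side chain of one residue with idealized internal-coordinate
#' geometry for the target residue type, leaving backbone coordinates (N, CA,
#' C, O, OXT) and every other residue untouched.  No rotamer optimization or
#' minimization is performed: chi angles default to a common rotamer, as the
#' mutant is meant as a topological starting point only.  For mutation to
#' proline the pyrrolidine ring (CB, CG, CD) is built with standard bond
#' lengths/angles; prolines carry no backbone amide hydrogen, so the backbone
#' N of the mutated residue stops being a hydrogen-bond donor (the contact
#' module's donor typing encodes this).
#'
#' Steric clashes of the new side chain (inter-atom distance below 0.6 times
#' the sum of Bondi radii against non-bonded atoms) are reported in the
#' `"clashes"` attribute but not repaired.
#'
#' @param s Structure.
#' @param mutation mutation spec string (see [parse_mutation()]) or the list it
#'   returns.
#' @return mutated Structure; attribute `"clashes"` holds a data frame of
#'   clashing atom pairs (possibly empty).
#' @export
mutate_residue <- function(s, mutation) {
  m <- if (is.character(mutation)) parse_mutation(mutation) else mutation
  rows <- which(s$atoms$chain == m$chain_id & s$atoms$resno == m$seq_number &
    s$atoms$insert == "")
  if (length(rows) == 0) {
    stop("target residue ", m$chain_id, ":", m$seq_number, " not found")
  }
  res <- s$atoms[rows, ]
  if (res$resname[1] != m$from_res) {
    stop(
      "identity mismatch: residue ", m$chain_id, ":", m$seq_number,
      " is ", res$resname[1], ", not ", m$from_res
    )
  }
  if (!m$to_res %in% STANDARD_AA) stop("target residue type ", m$to_res, " is not a standard amino acid")
  bb_needed <- c("N", "CA", "C", "O")
  if (!all(bb_needed %in% res$name)) {
    stop(
      "incomplete residue: backbone atom(s) ",
      paste(setdiff(bb_needed, res$name), collapse = ", "), " missing"
    )
  }
  if (m$from_res == m$to_res) {
    attr(s, "clashes") <- empty_clash_table()
    return(s)
  }

  bb_keep <- res$name %in% c("N", "CA", "C", "O", "OXT")
  getxyz <- function(nm) as.numeric(res[res$name == nm, c("x", "y", "z")][1, ])
  sc <- build_sidechain(m$to_res, getxyz("N"), getxyz("CA"), getxyz("C"))

  kept <- res[bb_keep, , drop = FALSE]
  kept$resname <- m$to_res
  new_rows <- kept[0, ]
  for (nm in names(sc)) {
    r <- kept[1, ]
    r$name <- nm
    r$x <- sc[[nm]][1]
    r$y <- sc[[nm]][2]
    r$z <- sc[[nm]][3]
    r$element <- infer_element(nm, m$to_res)
    r$occ <- 1
    r$b <- 0
    r$vdw <- NA_real_
    new_rows <- rbind(new_rows, r)
  }
  res_new <- rbind(kept, new_rows)
  res_new$is_sidechain <- !(res_new$name %in% BACKBONE_ATOMS)

  atoms <- s$atoms
  before <- atoms[seq_len(nrow(atoms)) < min(rows), , drop = FALSE]
  after <- atoms[seq_len(nrow(atoms)) > max(rows), , drop = FALSE]
  atoms <- rbind(before, res_new, after)
  atoms$eleno <- seq_len(nrow(atoms))
  out <- new_structure(atoms, model_id = s$model_id, metadata = s$metadata)
  if (!all(is.na(s$atoms$vdw))) {
    out <- assign_radii(out, "bondi")
  } else {
    out$atoms$vdw <- NA_real_
  }
  attr(out, "clashes") <- clash_report(out, m$chain_id, m$seq_number, names(sc))
  out
}

empty_clash_table <- function() {
  data.frame(
    atom_a = character(0), atom_b = character(0),
    distance = numeric(0), threshold = numeric(0)
  )
}

# clashes of the rebuilt side chain against atoms outside the mutated residue
clash_report <- function(s, chain, resno, sc_names) {
  bondi <- vdw_radius_table("bondi")
  rad_of <- function(el) {
    r <- bondi$radius[match(toupper(el), bondi$element)]
    r[is.na(r)] <- bondi$radius[bondi$element == "*"]
    r
  }
  a <- s$atoms
  in_res <- a$chain == chain & a$resno == resno & a$insert == ""
  sc_rows <- which(in_res & a$name %in% sc_names)
  other_rows <- which(!in_res)
  if (length(sc_rows) == 0 || length(other_rows) == 0) {
    return(empty_clash_table())
  }
  out <- empty_clash_table()
  xyz <- coords(s)
  r_all <- rad_of(a$element)
  for (i in sc_rows) {
    d <- sqrt(rowSums((xyz[other_rows, , drop = FALSE] -
      matrix(xyz[i, ], length(other_rows), 3, byrow = TRUE))^2))
    thr <- 0.6 * (r_all[i] + r_all[other_rows])
    hit <- which(d < thr)
    for (h in hit) {
      j <- other_rows[h]
      out <- rbind(out, data.frame(
        atom_a = paste0(chain, ":", resno, ":", a$name[i]),
        atom_b = paste0(a$chain[j], ":", a$resno[j], ":", a$name[j]),
        distance = d[h], threshold = thr[h]
      ))
    }
  }
  if (nrow(out) > 0) {
    message(nrow(out), " steric clash(es) after mutation (reported, not repaired)")
  }
  out
}
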
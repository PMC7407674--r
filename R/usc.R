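# Quasi-chemical statistical contact potential:
#   u_sc(i, j) = -kT * ln( N_obs(i, j) / (chi_i * chi_j * N_obs) )
# derived from the residue-pair composition of a library of binding
# interfaces. Counting is symmetrized (each contact counts once as (i, j)
# and once as (j, i)), which makes the mole fractions the marginals of the
# pair counts and keeps the table exactly symmetric.

#' Construct a statistical potential table
#'
#' @param u symmetric 20x20 numeric matrix (kT), dimnames = three-letter
#'   residue codes.
#' @param provenance free-text description of the table's origin.
#' @return Object of class `stat_potential_table`.
#' @export
stat_potential_table <- function(u, provenance = "") {
  stopifnot(is.matrix(u), all(dim(u) == c(20, 20)),
            identical(rownames(u), AA3), identical(colnames(u), AA3),
            all(is.finite(u)))
  if (max(abs(u - t(u))) > 1e-9) stop("u_sc table must be symmetric")
  u <- (u + t(u)) / 2
  structure(list(u = u, provenance = provenance),
            class = "stat_potential_table")
}

#' @export
print.stat_potential_table <- function(x, ...) {
  cat("Statistical contact potential (kT): 20x20,",
      sprintf("range [%.2f, %.2f]\n", min(x$u), max(x$u)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Derive the contact potential from a library of interfaces
#'
#' Counts residue-type pairs over all interfaces of the library, computes
#' interface mole fractions `chi_i` as the marginals of the (symmetrized)
#' pair counts, and applies the quasi-chemical inversion
#' `u_sc(i, j) = -ln(N_obs(i, j) / (chi_i chi_j N_obs))` in kT units.
#' Cells never observed receive a pseudo-count of 1 (avoids infinite
#' repulsion from sampling zeros); pair types whose residue types never
#' appear at all are assigned 0.
#'
#' @param contact_library a list of data.frames with columns `res_i`,
#'   `res_j` (three-letter codes), one row per interface contact, or a
#'   single such data.frame.
#' @param pseudocount added to zero cells of the symmetrized count matrix.
#' @return A `stat_potential_table`.
#' @export
derive_usc <- function(contact_library, pseudocount = 1) {
  if (is.data.frame(contact_library)) contact_library <- list(contact_library)
  if (length(contact_library) == 0) stop("empty contact library")
  all_pairs <- do.call(rbind, lapply(contact_library, function(d)
    d[, c("res_i", "res_j")]))
  if (nrow(all_pairs) == 0) stop("empty contact library")
  ti <- canonical_restype(all_pairs$res_i)
  tj <- canonical_restype(all_pairs$res_j)
  if (any(!(ti %in% AA3) | !(tj %in% AA3)))
    stop("non-standard residue type in contact library")

  # symmetrized ordered counts M(i,j): each contact counts in both orders
  f1 <- factor(ti, levels = AA3); f2 <- factor(tj, levels = AA3)
  M <- table(f1, f2) + table(f2, f1)
  M <- matrix(as.numeric(M), 20, 20, dimnames = list(AA3, AA3))
  Mtot <- sum(M)                     # = 2 * number of contacts
  chi <- rowSums(M) / Mtot           # interface mole fractions

  seen <- chi > 0
  expected <- Mtot * outer(chi, chi)
  ok <- outer(seen, seen, "&")
  Mp <- M
  Mp[M == 0 & ok] <- pseudocount
  u <- matrix(0, 20, 20, dimnames = list(AA3, AA3))
  u[ok] <- -log(Mp[ok] / expected[ok])
  stat_potential_table((u + t(u)) / 2,
                       provenance = sprintf(
                         "derived from %d interfaces, %d contacts",
                         length(contact_library), nrow(all_pairs)))
}

#' Read / write a statistical potential table as TSV
#'
#' The file holds 210 rows (unordered residue-type pairs) with columns
#' `res_i`, `res_j`, `u_sc` (kT), preceded by `#`-comment header lines
#' carrying provenance. The reader validates completeness and symmetry.
#'
#' @param path file path.
#' @return `read_usc_table()` returns a `stat_potential_table`;
#'   `write_usc_table()` returns `path` invisibly.
#' @export
read_usc_table <- function(path) {
  header <- character(0)
  lines <- readLines(path)
  header <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("res_i", "res_j", "u_sc") %in% names(df)))
  u <- matrix(NA_real_, 20, 20, dimnames = list(AA3, AA3))
  for (k in seq_len(nrow(df))) {
    i <- df$res_i[k]; j <- df$res_j[k]
    if (!(i %in% AA3) || !(j %in% AA3))
      stop("unknown residue type in table: ", i, "/", j)
    if (!is.na(u[i, j]) && abs(u[i, j] - df$u_sc[k]) > 1e-9)
      stop("conflicting duplicate entry for ", i, "-", j)
    u[i, j] <- df$u_sc[k]; u[j, i] <- df$u_sc[k]
  }
  if (any(is.na(u))) {
    miss <- which(is.na(u), arr.ind = TRUE)[1, ]
    stop("incomplete table: missing pair ", AA3[miss[1]], "-", AA3[miss[2]])
  }
  stat_potential_table(u, provenance = paste(header, collapse = " "))
}

#' @rdname read_usc_table
#' @param table a `stat_potential_table`.
#' @export
write_usc_table <- function(table, path) {
  stopifnot(inherits(table, "stat_potential_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(table$provenance))
    writeLines(paste("#", table$provenance), con)
  idx <- which(upper.tri(table$u, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(res_i = AA3[idx[, 1]], res_j = AA3[idx[, 2]],
                   u_sc = table$u[idx])
  df <- df[order(df$res_i, df$res_j), ]
  writeLines(paste(c("res_i", "res_j", "u_sc"), collapse = "\t"), con)
  writeLines(sprintf("%s\t%s\t%.10g", df$res_i, df$res_j, df$u_sc), con)
  invisible(path)
}

#' Default (synthetic) contact potential table
#'
#' Loads the table shipped with the package. It is derived from the
#' package's own synthetic contact-library pipeline (see
#' [make_contact_library()]) and is labelled as such; it is a working
#' default, not a reproduction of any published table.
#'
#' @return A `stat_potential_table`.
#' @export
default_usc_table <- function() {
  read_usc_table(system.file("extdata", "usc_synthetic.tsv",
                             package = "cgassoc", mustWork = TRUE))
}

# Quasi-chemical transform of a symmetric pair distribution: the table
# -ln(p_ij / (q_i q_j)) with q the marginals of p. Any table of this form
# is exactly what derive_usc() converges to when the library is sampled
# from p.
qc_transform <- function(p, provenance = "") {
  q <- rowSums(p)
  u <- -log(p / outer(q, q))
  dimnames(u) <- list(AA3, AA3)
  out <- stat_potential_table((u + t(u)) / 2, provenance = provenance)
  attr(out, "chi") <- q
  out
}
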
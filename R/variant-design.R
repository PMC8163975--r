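#' Propose a hotspot residue-swap variant
#'
#' Transplants one effector's hotspot residues onto another: at every
#' designated hotspot column where the donor and acceptor rows differ and
#' neither carries a gap, the acceptor residue is substituted by the donor
#' residue. Columns where the two agree are omitted; columns where either row
#' is gapped are reported as unswappable. Substitution positions are given in
#' the acceptor's construct numbering: the number of non-gap acceptor
#' residues up to the column, plus `numbering_offset` (so different acceptor
#' constructs can keep their own numbering frames).
#'
#' @param aln An [msa()] containing both rows.
#' @param donor,acceptor Row names (must differ).
#' @param hotspot_columns Integer set of hotspot column indices.
#' @param numbering_offset Integer added to the acceptor's residue count to
#'   obtain construct numbering (0 keeps 1-based counting).
#' @return Object of class `variant_proposal`: list with `donor`, `acceptor`,
#'   `substitutions` (data frame `position`, `acceptor_aa`, `donor_aa`,
#'   `column`, strictly increasing positions), `unswappable` (columns skipped
#'   because of gaps), `numbering_offset`.
#' @export
propose_swap <- function(aln, donor, acceptor, hotspot_columns,
                         numbering_offset = 0L) {
  stopifnot(inherits(aln, "msa"))
  if (identical(donor, acceptor))
    stop_config("donor and acceptor must be different rows")
  for (r in c(donor, acceptor))
    if (!r %in% aln$names) stop_data("row ", r, " not in alignment")
  hotspot_columns <- sort(unique(as.integer(hotspot_columns)))
  if (length(hotspot_columns) &&
      (min(hotspot_columns) < 1 || max(hotspot_columns) > aln$width))
    stop_config("hotspot columns outside the alignment width")

  d <- strsplit(unname(aln$seqs[donor]), "")[[1]]
  a <- strsplit(unname(aln$seqs[acceptor]), "")[[1]]
  acc_count <- cumsum(a != "-" & a != ".")

  subs <- data.frame(position = integer(), acceptor_aa = character(),
                     donor_aa = character(), column = integer())
  unswappable <- integer()
  for (j in hotspot_columns) {
    gap <- a[j] %in% c("-", ".") || d[j] %in% c("-", ".")
    if (gap) {
      unswappable <- c(unswappable, j)
    } else if (a[j] != d[j]) {
      subs <- rbind(subs, data.frame(
        position = acc_count[j] + numbering_offset,
        acceptor_aa = a[j], donor_aa = d[j], column = j))
    }
  }
  new_variant_proposal(donor, acceptor, subs, unswappable, numbering_offset)
}

#' @rdname propose_swap
#' @param substitutions Data frame (`position`, `acceptor_aa`, `donor_aa`)
#'   for directly constructed proposals; validation rejects duplicate or
#'   non-increasing positions and identical acceptor/donor residues.
#' @export
variant_proposal <- function(donor, acceptor, substitutions,
                             numbering_offset = 0L) {
  subs <- as.data.frame(substitutions)
  if (nrow(subs) && !"column" %in% names(subs)) subs$column <- NA_integer_
  new_variant_proposal(donor, acceptor, subs, integer(), numbering_offset)
}

new_variant_proposal <- function(donor, acceptor, subs, unswappable,
                                 numbering_offset) {
  if (nrow(subs)) {
    if (anyDuplicated(subs$position))
      stop_data("duplicate substitution positions: ",
                paste(unique(subs$position[duplicated(subs$position)]),
                      collapse = ", "))
    if (is.unsorted(subs$position, strictly = TRUE))
      stop_data("substitution positions must be strictly increasing")
    if (any(subs$acceptor_aa == subs$donor_aa))
      stop_data("acceptor and donor residues must differ in every substitution")
  }
  rownames(subs) <- NULL
  structure(list(donor = donor, acceptor = acceptor, substitutions = subs,
                 unswappable = unswappable,
                 numbering_offset = as.integer(numbering_offset)),
            class = "variant_proposal")
}

#' Format a variant proposal as a mutation string
#'
#' Joins `X<pos>Y` tokens with `/` in position order, e.g.
#' `"V40D/G42I/L43K/K45L/R46H"`; an empty proposal formats as `"wild-type"`.
#'
#' @param proposal A `variant_proposal`.
#' @return Character scalar.
#' @export
format_variant <- function(proposal) {
  stopifnot(inherits(proposal, "variant_proposal"))
  s <- proposal$substitutions
  if (nrow(s) == 0) return("wild-type")
  paste(sprintf("%s%d%s", s$acceptor_aa, s$position, s$donor_aa),
        collapse = "/")
}

#' @export
print.variant_proposal <- function(x, ...) {
  cat(sprintf("variant_proposal: %s-to-%s  %s\n", x$acceptor, x$donor,
              format_variant(x)))
  if (length(x$unswappable))
    cat("  unswappable columns:", paste(x$unswappable, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a variant proposal to the acceptor row
#'
#' Returns the acceptor's gapped sequence with the proposed substitutions
#' applied, for round-trip checks (re-proposing against the donor over the
#' same hotspot columns must then yield no substitutions).
#'
#' @param aln An [msa()].
#' @param proposal A `variant_proposal` created by [propose_swap()] on the
#'   same alignment (uses the recorded columns).
#' @return Gapped character scalar.
#' @export
apply_variant <- function(aln, proposal) {
  stopifnot(inherits(aln, "msa"), inherits(proposal, "variant_proposal"))
  a <- strsplit(unname(aln$seqs[proposal$acceptor]), "")[[1]]
  s <- proposal$substitutions
  if (nrow(s)) {
    if (any(is.na(s$column)))
      stop_data("proposal lacks column bookkeeping; build it with propose_swap")
    a[s$column] <- s$donor_aa
  }
  paste(a, collapse = "")
}
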
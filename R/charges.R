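# Partial charge assignment by bond-charge increments.
#
# Each bonded element pair carries a small charge increment flowing from
# the less to the more electronegative partner; an atom's partial charge
# is its formal charge plus the sum of increments over its bonds,
# multiplied by the bond order contribution (aromatic counted as 1.5).
# The table is a compact, documented stand-in in the MMFF94 spirit for
# the organic elements this package handles; values are not fitted.

.bci_electroneg <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                     P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66)

# increment per unit electronegativity difference per bond-order unit
.bci_scale <- 0.08

#' Assign partial charges by bond-charge increments
#'
#' Computes per-atom partial charges as formal charge plus a sum of
#' electronegativity-driven bond-charge increments over the atom's bonds
#' (aromatic bonds weighted 1.5).  Formal charges are therefore conserved:
#' the total partial charge equals the net formal charge.  Charges already
#' present on the molecule are only overwritten when `overwrite = TRUE`.
#'
#' @param mol A [molecule()].
#' @param overwrite Replace existing partial charges? Default `FALSE`.
#' @return The molecule with `partial_charge` filled in.
#' @export
assign_partial_charges <- function(mol, overwrite = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (!overwrite && all(is.finite(mol$atoms$partial_charge))) return(mol)
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), names(.bci_electroneg))
  if (length(unknown))
    stop("no electronegativity entry for element(s): ",
         paste(unknown, collapse = ", "))
  q <- as.numeric(mol$atoms$formal_charge)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      ord <- mol$bonds$order[k]
      w <- if (ord == 4L) 1.5 else as.numeric(ord)
      d <- .bci_scale * w * (.bci_electroneg[[el[j]]] - .bci_electroneg[[el[i]]])
      q[i] <- q[i] + d
      q[j] <- q[j] - d
    }
  }
  mol$atoms$partial_charge <- q
  mol
}
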
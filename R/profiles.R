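# Editor profiles: a parametric description of a base editor's chemistry --
# which PAM it needs and on which side, how long its protospacer is, where its
# activity window sits, and which conversion it performs.

#' Define a base-editor profile
#'
#' An editor profile captures everything the design and quantification code
#' needs to know about a base editor: the PAM pattern (IUPAC, e.g. `"NGG"` for
#' Cas9 nickase fusions, `"TTTV"` for Cas12a/Cpf1 fusions), which side of the
#' protospacer the PAM sits on, the protospacer length, the activity window in
#' protospacer coordinates (counted 1..length from the 5' end, so that for a
#' 3'-PAM editor the PAM occupies positions length+1..length+nchar(pam)), and
#' the conversion chemistry (A->G for adenine base editors, C->T for cytosine
#' base editors).
#'
#' @param name profile name.
#' @param pam IUPAC PAM pattern, e.g. `"NGG"` or `"TTTV"`.
#' @param pam_side `"three_prime"` or `"five_prime"` of the protospacer.
#' @param protospacer_len protospacer length in nt (20 for nCas9 fusions,
#'   23 for dCas12a).
#' @param window inclusive integer pair `c(lo, hi)`: the protospacer positions
#'   at which deamination occurs at useful rates.
#' @param edit_from,edit_to the conversion performed on the protospacer strand.
#' @return an object of class `editor_profile`.
#' @seealso [editor_profile()] for the built-in profiles.
#' @export
#' @examples
#' new_editor_profile("myABE", "NGG", "three_prime", 20, c(4, 10), "A", "G")
new_editor_profile <- function(name, pam, pam_side = c("three_prime", "five_prime"),
                               protospacer_len = 20L, window = c(4L, 10L),
                               edit_from = "A", edit_to = "G") {
  pam_side <- match.arg(pam_side)
  check_pam_pattern(pam)
  protospacer_len <- as.integer(protospacer_len)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2] ||
      window[2] > protospacer_len)
    stop("window must satisfy 1 <= lo <= hi <= protospacer_len")
  if (!edit_from %in% c("A", "C", "G", "T") || !edit_to %in% c("A", "C", "G", "T"))
    stop("edit_from/edit_to must be concrete bases")
  if (edit_from == edit_to) stop("edit_from and edit_to must differ")
  structure(list(name = name, pam = pam, pam_side = pam_side,
                 protospacer_len = protospacer_len, window = window,
                 edit_from = edit_from, edit_to = edit_to),
            class = "editor_profile")
}

#' Built-in base-editor profiles
#'
#' Retrieve one of the bundled profiles by name, or list all of them.
#' Bundled profiles:
#' \describe{
#'   \item{GhABE8e}{TadA8e--nCas9 adenine editor: NGG 3' PAM, 20-nt protospacer,
#'     activity window positions 4--10, A->G.}
#'   \item{GhABE8e-A4A12}{the same editor with the wider 4--12 window reported
#'     at some sites; kept as a named alternative, not the default.}
#'   \item{GhABE7.10}{TadA7.10--nCas9 adenine editor: NGG, 20 nt, narrow window
#'     at position 5 only, A->G.}
#'   \item{GhABE8e-dCpf1}{TadA8e--dCas12a adenine editor: TTTV 5' PAM, 23-nt
#'     protospacer, window 8--14 (provisional: taken from the ABE8e--dLbCas12a
#'     literature convention), A->G.}
#'   \item{CBE}{generic cytosine editor: NGG, 20 nt, window 4--8, C->T.}
#' }
#'
#' @param name profile name; `NULL` returns the full named list.
#' @return an `editor_profile`, or a named list of them.
#' @export
#' @examples
#' editor_profile("GhABE8e")
#' names(editor_profile())
editor_profile <- function(name = NULL) {
  builtins <- list(
    "GhABE8e"       = new_editor_profile("GhABE8e", "NGG", "three_prime", 20L, c(4L, 10L), "A", "G"),
    "GhABE8e-A4A12" = new_editor_profile("GhABE8e-A4A12", "NGG", "three_prime", 20L, c(4L, 12L), "A", "G"),
    "GhABE7.10"     = new_editor_profile("GhABE7.10", "NGG", "three_prime", 20L, c(5L, 5L), "A", "G"),
    "GhABE8e-dCpf1" = new_editor_profile("GhABE8e-dCpf1", "TTTV", "five_prime", 23L, c(8L, 14L), "A", "G"),
    "CBE"           = new_editor_profile("CBE", "NGG", "three_prime", 20L, c(4L, 8L), "C", "T")
  )
  if (is.null(name)) return(builtins)
  if (!name %in% names(builtins))
    stop("unknown profile '", name, "'; available: ", paste(names(builtins), collapse = ", "))
  builtins[[name]]
}

#' @export
print.editor_profile <- function(x, ...) {
  side <- if (x$pam_side == "three_prime") "3'" else "5'"
  cat(sprintf("<editor_profile> %s: %s->%s, PAM %s (%s), protospacer %d nt, window %d-%d\n",
              x$name, x$edit_from, x$edit_to, x$pam, side, x$protospacer_len,
              x$window[1], x$window[2]))
  invisible(x)
}
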
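## compound_library: the 26-compound agonist series and structure construction.
##
## The dataset is a congeneric series of tricyclic TRPA1 agonists sharing a
## dibenz-fused seven-membered ring whose azomethine (CH=N) closes the central
## ring; the bridge position (11, "A") carries O (oxazepine), CH2 (azepine) or
## S (thiazepine), and a single substituent sits at one of the numbered benzo
## positions 1-4 / 7-10.

# Scaffold SMILES template. Heavy-atom parse order fixes the position map:
#  1=N5, 2=C6 (azomethine CH), 3=C6a, 4=C7, 5=C8, 6=C9, 7=C10, 8=C10a,
#  9=C11 (bridge A), 10=C11a, 11=C1, 12=C2, 13=C3, 14=C4, 15=C4a.
.scaffoldTemplate <- "N1=Cc2c%sc%sc%sc%sc2%sc2c%sc%sc%sc%sc21"

.bridgeSmiles <- c(O = "O", CH2 = "C", S = "S")

# substituent token -> SMILES branch
.substituentSmiles <- c(
  "H"             = "",
  "COOMe"         = "(C(=O)OC)",
  "COOiPr"        = "(C(=O)OC(C)C)",
  "COOnBu"        = "(C(=O)OCCCC)",
  "CONH2"         = "(C(N)=O)",
  "CONH(CH2)3OMe" = "(C(=O)NCCCOC)",
  "CONEt2"        = "(C(=O)N(CC)CC)",
  "Br"            = "(Br)",
  "CN"            = "(C#N)",
  "OMe"           = "(OC)",
  "OH"            = "(O)")

#' Scaffold description for the tricyclic agonist series
#'
#' Returns the parent scaffold for a given bridge atom: its SMILES and the map
#' from ring position labels (1-4, 6-10, and the bridge label 11 alias "A") to
#' heavy-atom indices in SMILES parse order. The parent is a closed-shell
#' neutral tricyclic with exactly one C=N bond (the azomethine of the central
#' ring).
#'
#' @param bridge one of \code{"O"}, \code{"CH2"}, \code{"S"}.
#' @return list with elements \code{name}, \code{bridge}, \code{smiles},
#'   \code{positionMap} (named integer vector).
#' @examples
#' scaffoldSpec("O")$smiles
#' @export
scaffoldSpec <- function(bridge = c("O", "CH2", "S")) {
  bridge <- match.arg(bridge)
  name <- switch(bridge,
    O = "dibenz[b,f][1,4]oxazepine",
    CH2 = "11H-dibenz[b,e]azepine",
    S = "dibenz[b,f][1,4]thiazepine")
  list(name = name, bridge = bridge,
    smiles = sprintf(.scaffoldTemplate, "", "", "", "",
                     .bridgeSmiles[[bridge]], "", "", "", ""),
    positionMap = c("1" = 11L, "2" = 12L, "3" = 13L, "4" = 14L,
                    "6" = 2L, "7" = 4L, "8" = 5L, "9" = 6L, "10" = 7L,
                    "11" = 9L, "A" = 9L))
}

#' Convert an EC50 (molar) to pEC50
#'
#' pEC50 = log10(1 / EC50); strictly decreasing in EC50.
#'
#' @param ec50 numeric, half-maximal effective concentration in mol/L; must be
#'   positive.
#' @return numeric pEC50 (dimensionless log units).
#' @examples
#' pec50FromEc50(5e-7)   # 6.301
#' @export
pec50FromEc50 <- function(ec50) {
  if (!is.numeric(ec50) || any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("ec50 must be a positive finite concentration (mol/L)")
  log10(1 / ec50)
}

#' Convert a pEC50 back to EC50 (molar)
#' @param pec50 numeric pEC50.
#' @return numeric EC50 in mol/L.
#' @export
ec50FromPec50 <- function(pec50) 10^(-pec50)

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "fieldQSAR", mustWork = FALSE)
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install fallback
  p
}

#' Load the compound table of the agonist series
#'
#' Structure descriptors (substituent position/group, bridge atom) and actual
#' pEC50 for the 26 compounds, with train/test membership.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame with columns \code{id}, \code{position}, \code{group},
#'   \code{bridge}, \code{pec50}, \code{subset}.
#' @export
compoundTable <- function(path = .extdata("compounds.csv")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "position", "group", "bridge", "pec50", "subset")
  if (!all(need %in% names(tab))) stop("compound table missing columns")
  if (nrow(tab) != 26L) stop("expected 26 compound records, got ", nrow(tab))
  if (!setequal(tab$id[tab$subset == "test"], c(7, 13, 15, 16, 25)))
    stop("test subset must be compounds 7, 13, 15, 16, 25")
  if (any(tab$pec50 < 6.030 - 1e-9) || any(tab$pec50 > 10.301 + 1e-9))
    stop("pEC50 outside the series range 6.030..10.301")
  unknown <- setdiff(tab$group, names(.substituentSmiles))
  if (length(unknown))
    stop("unknown substituent token(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(.substituentSmiles), collapse = ", "))
  tab
}

#' SMILES for one compound of the series
#'
#' Grafts the substituent branch onto the scaffold template at the numbered
#' benzo position and installs the bridge atom at position 11 (A).
#'
#' @param position integer ring position 1-4 or 7-10, or \code{NA} for the
#'   unsubstituted parent.
#' @param group substituent token (e.g. \code{"COOMe"}, \code{"Br"},
#'   \code{"CN"}, \code{"CONH2"}, \code{"OMe"}, \code{"OH"}, \code{"H"}).
#' @param bridge bridge atom at position 11: \code{"O"}, \code{"CH2"} or
#'   \code{"S"}.
#' @return character(1) SMILES.
#' @examples
#' compoundSmiles(10, "COOMe", "O")
#' @export
compoundSmiles <- function(position, group, bridge) {
  if (!group %in% names(.substituentSmiles))
    stop("unknown substituent token '", group, "'; supported: ",
         paste(names(.substituentSmiles), collapse = ", "))
  if (!bridge %in% names(.bridgeSmiles))
    stop("bridge must be one of O, CH2, S")
  br <- stats::setNames(rep("", 8L), c("7", "8", "9", "10", "1", "2", "3", "4"))
  if (group != "H") {
    if (is.na(position) || !as.character(position) %in% names(br))
      stop("substituent position ", position,
           " absent from the scaffold position map (allowed: 1-4, 7-10)")
    br[[as.character(position)]] <- .substituentSmiles[[group]]
  }
  sprintf(.scaffoldTemplate, br[["7"]], br[["8"]], br[["9"]], br[["10"]],
          .bridgeSmiles[[bridge]], br[["1"]], br[["2"]], br[["3"]], br[["4"]])
}

#' SMILES for every compound in a compound table
#' @param tab a table from \code{\link{compoundTable}}.
#' @return named character vector (names = compound ids).
#' @export
compoundSmilesTable <- function(tab = compoundTable()) {
  stats::setNames(
    mapply(compoundSmiles, tab$position, tab$group, tab$bridge,
           USE.NAMES = FALSE),
    as.character(tab$id))
}

#' Load the activity / prediction table
#'
#' Actual pEC50, model-predicted pEC50 and residuals for both field models,
#' for all 26 compounds. Residual consistency (residual = actual - predicted,
#' up to last-digit rounding of the source table) is enforced.
#'
#' @param path CSV path; defaults to the packaged table.
#' @param tol rounding tolerance for the residual identity check.
#' @return data.frame with columns \code{id}, \code{pec50_actual},
#'   \code{pred_comfa}, \code{res_comfa}, \code{pred_comsia},
#'   \code{res_comsia}, \code{subset}.
#' @export
activityTable <- function(path = .extdata("predictions_table2.csv"),
                          tol = 0.0015) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("activity table is empty")
  if (nrow(tab) != 26L)
    stop("expected 26 activity rows, got ", nrow(tab))
  for (m in c("comfa", "comsia")) {
    d <- tab$pec50_actual - tab[[paste0("pred_", m)]] - tab[[paste0("res_", m)]]
    bad <- which(abs(d) > tol)
    if (length(bad))
      stop("residual inconsistency (", m, ") at compound id ",
           tab$id[bad[1]], ": actual - predicted != residual")
  }
  if (sum(tab$subset == "train") != 21L)
    stop("expected 21 training rows")
  tab
}

#' Published summary statistics of the two field models
#'
#' Reference internal (r2cv, r2, ONC, SEE, F, field contributions) and
#' external (r2pred, k, r0^2, rm^2, gap ratio) statistics of the CoMFA and
#' CoMSIA models of the packaged series, as a long-format table.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame with columns \code{model}, \code{statistic}, \code{value}.
#' @export
publishedModelStats <- function(path = .extdata("published_model_stats.csv")) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
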
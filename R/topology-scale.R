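# Uniform charge / sigma scaling of FFTopology objects. By default only
# molecules tagged "solvent-ion" are transformed: solutes keep their full
# charges and vdW radii, matching the standard scaled-charge IL protocol.

.checkTargets <- function(targets) {
  if (length(targets) == 0L)
    stop("empty target set: pass sQ/sSigma = 1 for an explicit no-op",
         call. = FALSE)
  bad <- setdiff(targets, c("solvent-ion", "solute", "other"))
  if (length(bad))
    stop(sprintf("unknown role tag(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  targets
}

#' @describeIn scaleCharges multiply atomic charges of molecules whose role
#'   is in `targets` by `sQ`; atom-type records, vdW and bonded terms are
#'   untouched.
#' @export
setMethod("scaleCharges", "FFTopology", function(object, sQ, targets = "solvent-ion") {
  stopifnot(is.numeric(sQ), length(sQ) == 1L)
  if (!(sQ > 0 && sQ <= 1.5))
    stop("charge-scaling factor must satisfy 0 < sQ <= 1.5", call. = FALSE)
  .checkTargets(targets)
  for (nm in names(object@molecules)) {
    if (object@molecules[[nm]]@role %in% targets)
      object@molecules[[nm]]@atoms$charge <-
        object@molecules[[nm]]@atoms$charge * sQ
  }
  validObject(object)
  object
})

# atom types used by molecules with / without a role in targets
.typeUsage <- function(top, targets) {
  tgt <- character(); oth <- character()
  for (m in top@molecules) {
    if (m@role %in% targets) tgt <- c(tgt, m@atoms$type)
    else oth <- c(oth, m@atoms$type)
  }
  list(target = unique(tgt), other = unique(oth))
}

#' @describeIn scaleSigma multiply sigma of all atom types used by target
#'   molecules by `sSigma`. Atom types shared with non-target molecules are
#'   refused: duplicate them first with [duplicateAtomTypes()].
#' @export
setMethod("scaleSigma", "FFTopology", function(object, sSigma, targets = "solvent-ion") {
  stopifnot(is.numeric(sSigma), length(sSigma) == 1L)
  if (!(sSigma >= 0.5 && sSigma <= 1.5))
    stop("sigma-scaling factor must satisfy 0.5 <= sSigma <= 1.5", call. = FALSE)
  .checkTargets(targets)
  use <- .typeUsage(object, targets)
  shared <- intersect(use$target, use$other)
  if (length(shared))
    stop(sprintf(paste0("atom type(s) %s are shared between target and ",
                        "non-target molecules; duplicate them first with ",
                        "duplicateAtomTypes()"),
                 paste(sprintf("'%s'", shared), collapse = ", ")),
         call. = FALSE)
  hit <- object@atomTypes$type %in% use$target
  object@atomTypes$sigma[hit] <- object@atomTypes$sigma[hit] * sSigma
  validObject(object)
  object
})

#' Duplicate atom types shared across scaling boundaries
#'
#' Clones every atom type used by both target and non-target molecules under
#' a suffixed name and rebinds the target molecules' atoms to the clone, so
#' that [scaleSigma()] can transform the targets without touching the others.
#'
#' @param top a [FFTopology-class].
#' @param targets role tags that define the scaling target set.
#' @param suffix appended to the cloned type names.
#' @return the modified topology (unchanged if nothing is shared).
#' @export
duplicateAtomTypes <- function(top, targets = "solvent-ion", suffix = "_scl") {
  stopifnot(is(top, "FFTopology"))
  .checkTargets(targets)
  use <- .typeUsage(top, targets)
  shared <- intersect(use$target, use$other)
  for (ty in shared) {
    newName <- paste0(ty, suffix)
    if (newName %in% top@atomTypes$type)
      stop(sprintf("cloned type name '%s' already exists", newName), call. = FALSE)
    row <- top@atomTypes[top@atomTypes$type == ty, , drop = FALSE]
    row$type <- newName
    top@atomTypes <- rbind(top@atomTypes, row)
    for (nm in names(top@molecules)) {
      m <- top@molecules[[nm]]
      if (m@role %in% targets) {
        m@atoms$type[m@atoms$type == ty] <- newName
        top@molecules[[nm]] <- m
      }
    }
  }
  validObject(top)
  top
}

#' @describeIn netCharge full-precision sum of the molecule's atomic charges.
#' @export
setMethod("netCharge", "FFTopology", function(object, molecule) {
  m <- getMolecule(object, molecule)
  sum(m@atoms$charge)
})
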
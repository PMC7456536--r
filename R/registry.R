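#' Default cysteine registry for nematode ZP modules
#'
#' Builds the registry of homologous cysteine columns in trimmed-alignment
#' coordinates. The core ZP-N disulfides are Cys1-Cys4 (columns 1 and 80,
#' linking the betaA and betaG strands) and Cys2-Cys3 (columns 29 and 48);
#' the canonical ZP-C set comprises Cys5 (146), Cys6 (164), Cys7 (201),
#' Cys8 (215 or 218, a replicate-dependent alternative pair), CysA (206)
#' and CysB (210). Novel sites implicated in connectivity changes are the
#' IHP pair (105 within the IHP motif, and 134), the Type-3 partner of
#' CysB in the betaC strand (140), the AB-loop pair (117/129, restricted
#' to one standalone ZP-C subfamily) and the FBN-1 partner (203).
#'
#' @param window Matching tolerance in columns (default 2): a cysteine
#'   within `window` of a registry column counts as occupying that site,
#'   absorbing replicate-alignment jitter.
#' @return A [CysteineRegistry-class] object.
#' @examples
#' reg <- defaultRegistry()
#' registrySites(reg)$name
#' @export
defaultRegistry <- function(window = 2L) {
  sites <- data.frame(
    name = c("Cys1", "Cys2", "Cys3", "Cys4",
             "Cys5", "Cys6", "Cys7", "Cys8", "CysA", "CysB",
             "IHP_A", "IHP_B", "T3_partner", "AB_loop", "FBN1_partner"),
    domain = c(rep("ZP-N", 4), rep("ZP-C", 11)),
    role = c(rep("core", 10), rep("novel", 5)),
    stringsAsFactors = FALSE
  )
  sites$columns <- list(1L, 29L, 48L, 80L,
                        146L, 164L, 201L, c(218L, 215L), 206L, 210L,
                        105L, 134L, 140L, c(117L, 129L), 203L)
  new("CysteineRegistry", sites = sites, window = as.integer(window))
}

#' @describeIn defaultRegistry Accessor for the site table.
#' @param registry A [CysteineRegistry-class].
#' @export
registrySites <- function(registry) {
  stopifnot(is(registry, "CysteineRegistry"))
  registry@sites
}

#' @describeIn defaultRegistry Accessor for the matching window.
#' @export
registryWindow <- function(registry) {
  stopifnot(is(registry, "CysteineRegistry"))
  registry@window
}

#' @describeIn defaultRegistry Primary column (first alternative) of a named site.
#' @param name Site name, e.g. `"Cys5"`.
#' @export
registryColumn <- function(registry, name) {
  s <- registrySites(registry)
  i <- match(name, s$name)
  if (is.na(i)) .stopf("unknown registry site '%s'", name)
  s$columns[[i]][1L]
}

# Columns that must carry a cysteine for each connectivity type.
# All types keep the ZP-N set and the Cys5-Cys7 / Cys6-Cys8 core;
# Type 2 adds the IHP pair; Type 3 additionally swaps CysA for the
# betaC partner at 140 while retaining CysB.
.typeLayout <- function(type) {
  base <- c("Cys1", "Cys2", "Cys3", "Cys4", "Cys5", "Cys6", "Cys7", "Cys8")
  switch(type,
    Type1 = c(base, "CysA", "CysB"),
    Type2 = c(base, "CysA", "CysB", "IHP_A", "IHP_B"),
    Type3 = c(base, "CysB", "IHP_A", "IHP_B", "T3_partner"),
    .stopf("unknown connectivity type '%s'", type)
  )
}

# Primary columns required to carry C for a type (used by the generator).
.typeColumns <- function(registry, type) {
  vapply(.typeLayout(type), function(nm) registryColumn(registry, nm), integer(1))
}

# All registry columns (all alternatives), e.g. to keep background gaps away.
.allRegistryColumns <- function(registry) {
  sort(unique(unlist(registrySites(registry)$columns)))
}

# Disulfide pairs planted per type (column pairs, primary columns).
# Type 1: Cys5-Cys7, Cys6-Cys8, CysA-CysB.
# Type 2: the same plus the IHP pair 105-134.
# Type 3: Cys5-Cys7, Cys6-Cys8, IHP pair, and CysB re-paired with 140.
.typeDisulfidePairs <- function(registry, type) {
  cc <- function(a, b) c(registryColumn(registry, a), registryColumn(registry, b))
  pairs <- switch(type,
    Type1 = list(cc("Cys5", "Cys7"), cc("Cys6", "Cys8"), cc("CysA", "CysB")),
    Type2 = list(cc("Cys5", "Cys7"), cc("Cys6", "Cys8"), cc("CysA", "CysB"),
                 cc("IHP_A", "IHP_B")),
    Type3 = list(cc("Cys5", "Cys7"), cc("Cys6", "Cys8"),
                 cc("T3_partner", "CysB"), cc("IHP_A", "IHP_B")),
    .stopf("unknown connectivity type '%s'", type)
  )
  do.call(rbind, pairs)
}

setMethod("show", "CysteineRegistry", function(object) {
  s <- object@sites
  cat("CysteineRegistry with", nrow(s), "sites (window +/-",
      object@window, "columns)\n")
  cols <- vapply(s$columns, function(x) paste(x, collapse = "/"), character(1))
  cat(paste0("  ", format(s$name, width = 13), " ", format(s$domain, width = 5),
             " ", format(s$role, width = 5), " col ", cols, collapse = "\n"), "\n")
})
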
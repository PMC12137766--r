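# Shared fixtures, built once per test run. Everything is generated in
# code; the cache only avoids recomputing the same phantom or signal pair
# across test files.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

gmTissue <- function() tissueParams("GM", 1900, 0.85)
wmTissue <- function() tissueParams("WM", 1200, 0.70)

phantom32 <- function() fixture("ph32", function()
  makePhantom(c(32L, 32L, 32L), seed = 2L))

proto32 <- function() fixture("p32", function() demoProtocol(rep(32L, 3)))

# single-shot-per-block variant: one excitation exactly at each TI
singleShotProtocol <- function() fixture("pss", function()
  protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23, trIR = 3097,
                 fa1 = 10, fa2 = 10, shotsPerTiBlock = 1L, tag = "single"))

# noise-free ideal signal volumes of the 32-cube phantom (uniform B1)
idealPair32 <- function() fixture("ideal32", function() {
  ph <- phantom32()
  phU <- ph
  phU@b1Map[] <- 1
  p <- proto32()
  list(s1 = epiT1:::idealImage(phU, p, 1L),
       s2 = epiT1:::idealImage(phU, p, 2L), phantom = phU, protocol = p)
})
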
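# Shared fixtures, built once per test run. The default 96^3 phantom and its
# plan are reused across files to keep the suite inside the time budget.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixPhantom <- function() fixture("phantom", function() {
  makeHeadPhantom(phantomConfig())
})

fixVolume <- function() fixPhantom()$volume

fixVesselMask <- function() fixture("vesselMask", function() {
  rasteriseVessels(fixPhantom()$vessels, fixVolume()@grid)@labels != 0L
})

fixPlan <- function() fixture("plan", function() {
  planCallosotomy(fixVolume(), fixVesselMask())
})

fixStreams <- function() fixture("streams", function() {
  makeInterhemisphericStreamlines(fixVolume(), n = 5000L, seed = 7L)
})

fixCavity <- function() fixture("cavity", function() {
  combinedCavity(fixPlan(), roleMask(fixVolume(), "corpus_callosum"),
                 fixVolume()@grid)
})

fixReport <- function() fixture("report", function() {
  vol <- fixVolume()
  assessPlan(fixPlan(), fixStreams(), roleMask(vol, "corpus_callosum"),
             vol@grid, cavityMask = fixCavity()$mask)
})
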
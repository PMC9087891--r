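## Shared fixtures built in code.

modelFile <- function(name)
  system.file("extdata", name, package = "msciTowers")

basicBdiModel <- function() readMSciModel(modelFile("bdi2_basic.msci"))
doubleBdiModel <- function() readMSciModel(modelFile("bdi2_double.msci"))
fiveSistersModel <- function() readMSciModel(modelFile("bdi5_sisters.msci"))
fiveMixedModel <- function() readMSciModel(modelFile("bdi5_mixed.msci"))
threeNonsisterModel <- function() readMSciModel(modelFile("bdi3_nonsister2.msci"))
udiNetworkModel <- function() readMSciModel(modelFile("udi4_network.msci"))

noFlowModelText <- c(
  "tree ((A,B)R;)",
  "tau R=0.01",
  "theta A=0.01 B=0.01 R=0.01")

## transforms of the basic single-BDI event
basicMappings <- function() {
  ev <- detectBdiEvents(basicBdiModel())[[1]]
  list(identityMapping(), singleBdiMapping(ev))
}

doubleMappings <- function() {
  ev <- detectBdiEvents(doubleBdiModel())
  doubleBdiMappings(ev[[1]], ev[[2]])
}

## well-separated twin-tower fixture: high beta/gamma concentration so the
## towers barely overlap (phi means 0.7/0.2, theta means 0.005/0.02)
separatedSpec <- function(n = 10000L, stay = 0.99)
  towerSpec(phi = list(phi_X = c(70, 30), phi_Y = c(20, 80)),
            theta = list(theta_X = c(100, 20000), theta_Y = c(100, 5000)),
            weights = c(0.5, 0.5), stay = stay, n = n)

## well-separated four-tower double-BDI fixture
separatedDoubleSpec <- function(n = 10000L, stay = 0.99)
  towerSpec(phi = list(phi_X = c(20, 180), phi_Y = c(40, 160),
                       phi_Z = c(40, 160), phi_W = c(60, 140)),
            theta = list(theta_X = c(100, 20000), theta_Y = c(100, 5000),
                         theta_Z = c(100, 20000), theta_W = c(100, 5000)),
            weights = rep(0.25, 4), stay = stay, n = n)

## random sample table over the basic event columns (for property tests)
randomEventTable <- function(n = 200L) {
  data.frame(phi_X = runif(n), phi_Y = runif(n),
             theta_X = rgamma(n, 2, 200), theta_Y = rgamma(n, 2, 100))
}

randomParamVector <- function() {
  v <- c(runif(2), rgamma(2, 2, 100), runif(2), rgamma(2, 2, 100))
  names(v) <- c("phi_X", "phi_Y", "theta_X", "theta_Y",
                "phi_Z", "phi_W", "theta_Z", "theta_W")
  v
}
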
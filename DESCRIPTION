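Package: surgesim
Title: Discrete-Event Simulation of Hospital Surge Capacity in
    Mass-Casualty Incidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico surge-capacity test bench for hospitals facing
    mass-casualty incidents.  Synthetic casualties carrying injuries,
    trauma scores (ISS, NISS, RTS), time- and treatment-dependent
    physiology and per-treatment deadlines are evacuated from an incident
    scene by a finite ambulance fleet and flow through emergency
    department trauma units, computed tomography, operating theatres,
    intensive care and wards under finite, time-mobilized staff and
    material resources.  A discrete-event engine counts preventable
    deaths and complications caused by missed treatment deadlines, and a
    capacity search determines, per hospital component and response
    phase, the largest casualty load manageable without preventable
    mortality.  A regional coordination layer implements predictive
    ("one step ahead") inflow control and casualty-distribution policies
    across several hospitals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
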
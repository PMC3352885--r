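taxon_set,group,s,delta_plus
diplopod,Polyxenida,108,82.81
diplopod,Glomeridesmida,32,41.54
diplopod,Glomerida,283,71.76
diplopod,Sphaerotheriida,332,79.21
diplopod,Platydesmida,68,76.76
diplopod,Polyzoniida,130,62.9
diplopod,Siphonophorida,121,45.72
diplopod,Siphonocryptida,3,31.25
diplopod,Siphoniulida,2,25
diplopod,Julida,1342,88.1
diplopod,Spirobolida,1247,89
diplopod,Spirostreptida,1906,88.42
diplopod,Chordeumatida,1138,96.7
diplopod,Callipodida,125,85.07
diplopod,Stemmiulida,144,56
diplopod,Polydesmida,5070,96.26
chilopod,Scutigeromorpha,206,71.61
chilopod,Lithobiomorpha,1861,60.89
chilopod,Craterostigmomorpha,1,0
chilopod,Scolopendromorpha,1328,78.3
chilopod,Geophilomorpha,1665,90.53
pseudoscorpion,Pseudoscorpiones,3432,95.62
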
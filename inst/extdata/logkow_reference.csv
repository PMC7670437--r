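name,logkow_cosmosac,logkow_fh,logkow_exp
Aceclofenac,1.57,-1.31,2.17
Acetaminophen,0.02,-1.56,0.46
Atropine,0.65,-1.74,1.83
Camphor,1.16,-1.4,2.38
Cefixime,-2.22,-1.04,-0.40
Celecoxib,2.83,-2.48,3.53
Dapsone,0.33,-1.29,0.97
Deferiprone,-0.94,-1.14,-0.77
Flurbiprofen,1.34,-1.73,4.16
Hydroquinone,0.57,-3.4,0.59
Isoniazid,-0.98,-3.22,-0.70
Lamotrigine,0.82,-2.13,2.57
Meclofenamic acid,2.83,-2.17,5.00
Pindolol,1.43,-3.70,1.75
p-Nitrobenzamide,0.07,-0.89,0.82
Sulfamethazine,0.99,-1.69,0.89
Borneol,1.78,-1.3,3.24
Carvedilol,2.66,-0.83,4.19
Ibuprofen,2.03,-1.91,3.97
Isoborneol,2.35,-3.00,3.24
Sulfacetamide,-0.04,-1.68,-0.96
Trifloxystrobin,3.86,-3.4,4.50
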
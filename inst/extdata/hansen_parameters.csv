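name,kind,delta_t,delta_d,delta_p,delta_h,V,V_cosmo,ambiguous
1-Propanol,solvent,24.5,16,6.8,17.4,75.2,52.6,FALSE
2-Propanol,solvent,23.5,15.8,6.1,16.4,76.8,52.64,FALSE
Acetic Acid,solvent,21.4,14.5,8,13.5,57.1,43.38,FALSE
Acetone,solvent,20,15.5,10.4,7,74.0,49.92,FALSE
Acetonitrile,solvent,24.4,15.3,18,6.1,52.6,38.41,FALSE
Ethanol,solvent,26.5,15.8,8.8,19.4,58.5,40.33,FALSE
Ethyl Acetate,solvent,18.1,15.8,5.3,7.2,98.5,68.14,FALSE
Heptane,solvent,15.3,15.3,0,0,147.4,94.24,FALSE
Hexane,solvent,14.9,14.9,0,0,131.6,82.11,FALSE
Methanol,solvent,29.6,15.1,12.3,22.3,40.7,29.09,FALSE
Methyl Acetate,solvent,18.7,15.5,7.2,7.6,79.7,56.13,FALSE
Octanol,solvent,21,17,3.3,11.9,157.7,112.43,FALSE
Water,solvent,47.8,15.6,16,42.3,18.0,15.2,FALSE
2-Phenylacetamide,drug,27.89,22.54,16.38,1.2,53.63,98.25,FALSE
4-Methylphthalic anhydride,drug,32.45,27.18,17.7,1.02,66.0,103.50,FALSE
Aceclofenac,drug,28.02,26.64,8.65,0.79,121.83,213.03,FALSE
Acetaminophen,drug,28.24,23.37,15.75,1.85,60.07,104.32,FALSE
Acetylsalicylic acid,drug,29.06,27.45,9.46,1.15,70.63,116.83,FALSE
Atenolol,drug,21.38,20.23,6.88,0.81,161.3,190.11,FALSE
Atropine,drug,27.78,26.84,7.11,1.03,103.07,195.58,FALSE
Benzamide,drug,35.25,25.7,24.05,1.76,36.53,86.76,FALSE
Camphor,drug,20.59,19.29,7.21,0.29,106.7,111.53,FALSE
Capecitabine,drug,24.65,22.83,9.26,0.83,205.94,225.47,FALSE
Cefixime,drug,30.18,27.82,11.67,0.86,190.56,264.81,FALSE
Cephalexin,drug,33.22,29.67,14.91,0.99,111.46,219.59,FALSE
Cimetidine,drug,27.39,22.85,15.1,0.61,162.3,176.03,FALSE
Deferiprone,drug,22.59,19.64,11.09,1.25,83.97,95.13,FALSE
Flurbiprofen,drug,24.56,23.03,8.49,0.86,82.33,164.03,FALSE
Hydroquinone,drug,43.64,31.25,29.89,5.87,23.84,75.95,FALSE
Isoniazid,drug,44.85,27.74,35.19,1.89,45.53,93.62,FALSE
Lamotrigine,drug,40.17,29.09,27.67,1.23,90.26,147.47,FALSE
Meclofenamic acid,drug,25.08,23.52,8.69,0.78,106.43,177.91,FALSE
Pentoxifylline,drug,23.76,21.49,10.14,0.4,187.2,184.38,TRUE
Pindolol,drug,23.46,21.41,9.55,0.92,129.37,177.38,FALSE
p-Nitrobenzamide,drug,36.71,26.8,25.05,1.28,55.33,104.25,FALSE
Vinpocetine,drug,32.28,31.84,5.28,0.43,108.8,235.71,FALSE
Benzocaine,drug,27.88,26.5,8.64,0.91,77.33,115.91,FALSE
Borneol,drug,19.15,18.54,4.68,0.93,106.67,115.13,FALSE
Carvedilol,drug,25.27,24.45,6.32,0.9,146.27,274.61,TRUE
Ibuprofen,drug,18.35,18.09,3.07,0.5,140.43,154.87,FALSE
Isoborneol,drug,20.06,19.48,4.72,0.94,105.67,114.97,FALSE
Salicylic acid,drug,30.52,25.83,16,2.94,41.2,90.21,TRUE
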
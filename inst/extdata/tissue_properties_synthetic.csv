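name,density_kg_m3,speed_m_s,length_m,reference
epidermis,1109,1513,0.0002,synthetic: impedance pinned by reported epidermis pressure/intensity pairs
dermis,1109,1540,0.002,synthetic: literature-typical skin
subcutaneous_tissue,911,1440,0.005,synthetic: literature-typical fat
cervical_vagus_trunk,1075,1630,0.10,synthetic: nerve impedance pinned by reported terminal intensities; length approximate anatomy
lrln_descending,1075,1630,0.12,synthetic: nerve; recurrent laryngeal descent
lrln_loop,1075,1630,0.04,synthetic: nerve; loop under aortic arch
lrln_terminal,1075,1630,0.14,synthetic: nerve; ascent to larynx
thoracic_vagus_trunk,1075,1630,0.12,synthetic: nerve
cardiac_branch,1075,1630,0.05,synthetic: nerve
anterior_vagal_trunk,1075,1630,0.10,synthetic: nerve
esophageal_plexus,1075,1630,0.06,synthetic: nerve
celiac_branch,1075,1630,0.04,synthetic: nerve
celiac_plexus,1075,1630,0.03,synthetic: nerve
splenic_nerve,1075,1630,0.04,synthetic: nerve
hepatic_branch,1075,1630,0.05,synthetic: nerve
hepatic_plexus,1075,1630,0.04,synthetic: nerve
gastric_branch,1075,1630,0.04,synthetic: nerve
gastric_plexus,1075,1630,0.03,synthetic: nerve
intercostal_muscle,1090,1580,0.015,synthetic: literature-typical muscle
diaphragm,1090,1580,0.005,synthetic: literature-typical muscle
spleen_capsule,1100,1570,0.001,synthetic: literature-typical connective tissue
spleen,1089,1567,0.055,synthetic: literature-typical spleen
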
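# Synthetic adult-male phantom geometry for building a Tc-99m S-value table.
# This is NOT a published phantom: organ centroids (cm; x lateral, y
# anterior-posterior, z caudal-cranial with z = 0 at the pubic symphysis)
# and reference masses (g) are plausible adult-male values chosen so that
# a simple point-source photon transport model yields S-values of realistic
# magnitude. kind: point = compact organ treated as a point/sphere,
# distributed = spread through the body, contents = hollow-organ contents.
organ,mass_g,x_cm,y_cm,z_cm,kind,is_source,is_target
adrenals,16,0,-6,36,point,FALSE,TRUE
brain,1420,0,0,78,point,FALSE,TRUE
breasts,26,0,10,46,point,FALSE,TRUE
gallbladder_wall,10,-5,4,30,point,FALSE,TRUE
lli_wall,160,4,0,12,point,FALSE,TRUE
small_intestine,640,0,2,18,point,FALSE,TRUE
stomach_wall,150,6,4,33,point,FALSE,TRUE
uli_wall,210,-4,1,20,point,FALSE,TRUE
heart,500,4,4,44,point,TRUE,FALSE
heart_wall,330,4,4,44,point,FALSE,TRUE
kidneys,299,0,-7,29,point,TRUE,TRUE
liver,1810,-6,2,33,point,TRUE,TRUE
lungs,1000,0,0,45,point,TRUE,TRUE
muscle,28000,0,0,30,distributed,FALSE,TRUE
pancreas,94,2,0,31,point,TRUE,TRUE
red_marrow,1120,0,-6,30,point,TRUE,TRUE
osteogenic_cells,120,0,-4,30,point,FALSE,TRUE
skin,2600,0,0,30,distributed,FALSE,TRUE
spleen,183,9,-2,33,point,TRUE,TRUE
testes,35,0,2,-4,point,FALSE,TRUE
thymus,25,0,6,50,point,FALSE,TRUE
thyroid,21,0,4,58,point,FALSE,TRUE
urinary_bladder_wall,48,0,3,6,point,FALSE,TRUE
urinary_bladder_contents,200,0,3,6,contents,TRUE,FALSE
total_body,73000,0,0,35,distributed,TRUE,TRUE
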
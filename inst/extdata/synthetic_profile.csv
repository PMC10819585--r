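"site","layer","Cr","Ni","Cu","Zn","As","Cd","Pb"
"S1","APMS",43.7303566233664,191.009784559376,47.4802573255282,171.955149247156,12.4915837522122,0.897499740540429,27.6098669662487
"S2","APMS",51.5662490876339,197.749530205842,70.2735850029548,267.747598447994,15.102127007555,1.44431027959167,34.5899355715869
"S3","APMS",41.4342585073576,179.71416007595,30.7654258409807,183.953057837362,13.9241134504182,0.738787091243172,23.7533742005523
"S4","APMS",67.6949714759404,210.105140235946,51.8099750992729,362.545667589307,18.1784171924157,1.32173201004521,37.8012554132485
"S5","APMS",56.4998532355765,200.2974959885,47.385218456582,257.810805187458,16.5033422705057,1.39441692866563,29.350734435048
"S6","APMS",42.6439257669137,203.249440170583,45.5637688805845,306.661895450676,13.2510173654301,0.952323629369616,28.1832651019056
"S7","APMS",77.2137395407209,255.69650942001,158.274640728796,430.12744157723,20.3771290748406,1.3783953917695,49.2562720080578
"S8","APMS",56.1766457624906,208.897939343792,80.0471286653012,334.478384662818,16.0282698866225,0.904534928774759,44.6312963033523
"S1","SOIL",33.9809429104569,177.578257366436,28.2241995644024,147.453475918294,8.31351326276173,0.737226530972703,26.6398067730845
"S2","SOIL",47.5593279437707,202.025062730649,58.1525178029646,280.630556990287,12.8036814903312,0.79389305429942,25.0689101546413
"S3","SOIL",65.6378998262938,180.739806509705,61.8134006844856,213.567363077717,13.3983715625766,1.59164619937842,43.2890444242207
"S4","SOIL",43.7397596522398,197.847272769552,23.8412183380512,190.446713490771,17.6456898707894,0.72402905395968,21.4753756619528
"S5","SOIL",38.031359992528,188.47250077759,39.616780609765,193.290729760663,12.7020992013489,1.10060515742078,34.7522960554504
"S6","SOIL",43.9847261730057,194.494871047685,48.7005566673415,200.234435849825,18.26516274869,0.882336097189767,21.3945509560559
"S7","SOIL",31.8124888177989,202.854682624633,46.9001147459767,206.168057432531,14.8063550762794,1.1757598117776,38.2292821317012
"S8","SOIL",55.4934946839062,205.82754617375,56.351211587013,229.168667479912,16.7051267872228,0.986504095001632,37.4707338428932
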
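node	START	G1	S	G2	M	stationary_G1
CLN3	0.98	0.02	0.20113571875	0.1	0.1520875	0.20113571875
MBF	0.115	0.430128081048501	0.79886428125	0.9	0.1520875	0.034980125
SBF	0.115	0.430128081048501	0.79886428125	0.9	0.1520875	0.034980125
CLN12	0.115	0.401715290060551	0.79886428125	0.9	0.7604375	0.20113571875
CLB56	0.115	0.02	0.98	0.9	0.7604375	0.20113571875
CLB12	0.115	0.02	0.20113571875	0.9	0.98	0.20113571875
MCM1SFF	0.115	0.202116983701807	0.20113571875	0.9	0.8479125	0.20113571875
CDC20	0.115	0.212393950654895	0.20113571875	0.1	0.8479125	0.20113571875
CDC14	0.115	0.0603620615103737	0.20113571875	0.1	0.1520875	0.0304175
SWI5	0.02	0.367754935249693	0.20113571875	0.1	0.1520875	0.02
CDH1	0.885	0.396167726237643	0.20113571875	0.1	0.1520875	0.79886428125
SIC1	0.885	0.406444693190731	0.20113571875	0.1	0.1520875	0.79886428125
ESP1	0.115	0.26247904521218	0.20113571875	0.1	0.02	0.0304175
PDS1	0.885	0.777329082392017	0.79886428125	0.9	0.7604375	0.79886428125
SPO12	0.115	0.212393950654895	0.20113571875	0.1	0.8479125	0.20113571875
CDC5	0.115	0.212393950654895	0.20113571875	0.1	0.8479125	0.20113571875
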
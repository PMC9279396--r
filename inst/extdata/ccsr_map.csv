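"code","ccsr_category"
"F320","MBD002"
"F321","MBD002"
"F329","MBD002"
"F331","MBD002"
"F339","MBD002"
"F300","MBD003"
"F309","MBD003"
"F319","MBD003"
"F3181","MBD003"
"F341","MBD004"
"F348","MBD004"
"F39","MBD004"
"F410","MBD005"
"F411","MBD005"
"F419","MBD005"
"F4010","MBD005"
"F4310","MBD007"
"F4312","MBD007"
"F4321","MBD007"
"F439","MBD007"
"F639","MBD008"
"F919","MBD008"
"F603","MBD009"
"F600","MBD009"
"F609","MBD009"
"F21","MBD009"
"R45851","MBD012"
"T1491","MBD012"
"X789","MBD027"
"X710","MBD027"
"F1010","MBD017"
"F1020","MBD017"
"F1110","MBD018"
"F1120","MBD018"
"F1210","MBD019"
"F1220","MBD019"
"F1310","MBD020"
"F1510","MBD021"
"F1610","MBD022"
"F1810","MBD023"
"F1910","MBD025"
"F1920","MBD025"
"F209","MBD001"
"F250","MBD001"
"F29","MBD001"
"F059","MBD031"
"F0630","MBD031"
"F70","MBD026"
"F72","MBD026"
"E119","END002"
"E039","END002"
"E669","END009"
"I10","CIR007"
"I2510","CIR011"
"J45909","RSP009"
"J069","RSP006"
"M545","MUS010"
"M179","MUS006"
"K219","DIG004"
"R51","SYM006"
"N390","GEN004"
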
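"code","rating"
"F320","positive"
"F321","positive"
"F329","positive"
"F331","positive"
"F339","unsure"
"F300","positive"
"F309","positive"
"F319","positive"
"F3181","positive"
"F341","unsure"
"F348","unsure"
"F39","unsure"
"F410","positive"
"F411","unsure"
"F419","positive"
"F4010","unsure"
"F4310","positive"
"F4312","positive"
"F4321","unsure"
"F439","positive"
"F639","positive"
"F919","unsure"
"F603","positive"
"F600","positive"
"F609","positive"
"F21","unsure"
"R45851","positive"
"T1491","positive"
"X789","positive"
"X710","positive"
"F1010","unsure"
"F1020","negative"
"F1110","unsure"
"F1120","negative"
"F1210","unsure"
"F1220","negative"
"F1310","negative"
"F1510","negative"
"F1610","negative"
"F1810","negative"
"F1910","unsure"
"F1920","negative"
"F209","negative"
"F250","negative"
"F29","negative"
"F059","unrelated"
"F0630","unrelated"
"F70","unrelated"
"F72","unrelated"
"E119","unrelated"
"E039","unrelated"
"E669","unrelated"
"I10","unrelated"
"I2510","unrelated"
"J45909","unrelated"
"J069","unrelated"
"M545","unrelated"
"M179","unrelated"
"K219","unrelated"
"R51","unrelated"
"N390","unrelated"
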